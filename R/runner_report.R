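#' The seven pairwise condition comparisons
#'
#' Each movement and imagery condition against rest, imagery foot vs hand,
#' movement foot vs hand, and observation foot vs hand (the negative
#' control: it should classify at chance).
#'
#' @return list of character(2) pairs, named `"IF-RS"` etc.
#' @export
condition_pairs <- function() {
  pairs <- list(
    c("IF", "RS"), c("IH", "RS"), c("MF", "RS"), c("MH", "RS"),
    c("IF", "IH"), c("MF", "MH"), c("OF", "OH")
  )
  stats::setNames(pairs, vapply(pairs, paste, "", collapse = "-"))
}

#' Enumerate the experimental grid
#'
#' One cell per (recording, comparison, montage) for each feature kind,
#' each with a deterministically derived seed. 36 recordings x 7
#' comparisons x 4 montages give 1,008 cells per feature kind.
#'
#' @param recording_ids character vector of recording identifiers.
#' @param comparisons list of condition pairs (default [condition_pairs()]).
#' @param montages character vector of montage names (default all four).
#' @param feature_kinds subset of `c("FFT", "ffDTF")`.
#' @param seed base seed; per-cell seeds are derived from it.
#' @return tibble with columns `cell_id`, `recording`, `comparison`,
#'   `montage`, `feature_kind`, `seed`.
#' @export
build_grid <- function(recording_ids,
                       comparisons = condition_pairs(),
                       montages = c("LD-SM", "LD-whole", "HD-SM", "HD-whole"),
                       feature_kinds = c("FFT", "ffDTF"),
                       seed = 1) {
  stopifnot(length(recording_ids) >= 1)
  grid <- expand.grid(
    comparison = names(comparisons),
    montage = montages,
    feature_kind = feature_kinds,
    recording = recording_ids,
    stringsAsFactors = FALSE
  )
  grid <- tibble::as_tibble(grid[, c(
    "recording", "comparison", "montage",
    "feature_kind"
  )])
  grid$cell_id <- seq_len(nrow(grid))
  grid$seed <- vapply(grid$cell_id, function(i) derive_seed(seed, i), integer(1))
  grid[, c("cell_id", "recording", "comparison", "montage", "feature_kind", "seed")]
}

#' Run the classification grid over a set of recordings
#'
#' For each recording: high-pass filter (1 Hz), optional 50 Hz notch,
#' epoch, sub-segment; then for each montage and feature kind build the
#' feature table once and run [nested_classify()] for every comparison in
#' the grid. Cells that error are logged and reported with NA scores
#' rather than aborting the grid; cells already present in `done` are
#' skipped, making reruns resumable.
#'
#' @param recordings named list of `eeg_recording` objects (names must
#'   match `grid$recording`), or a character vector of container stems for
#'   [read_recording()].
#' @param grid a [build_grid()] tibble.
#' @param montages montage definitions from [load_montages()].
#' @param params a [classify_params()].
#' @param notch apply the 50 Hz notch filter (default TRUE).
#' @param done previous results tibble to resume from (optional).
#' @param verbose print one line per cell.
#' @return list with `results` (tibble: recording, group, session,
#'   comparison, montage, feature_kind, h0, n, accuracy, sensitivity,
#'   specificity, n_features, seed) and `selections` (tibble of consensus
#'   features per cell, labelled via the feature index map).
#' @export
run_experiment <- function(recordings, grid, montages = load_montages(),
                           params = classify_params(), notch = TRUE,
                           done = NULL, verbose = FALSE) {
  comparisons <- condition_pairs()
  by_path <- is.character(recordings)
  rec_names <- if (by_path) basename(recordings) else names(recordings)
  stopifnot(all(grid$recording %in% rec_names))
  results <- list()
  sels <- list()
  for (rec_name in unique(grid$recording)) {
    sub <- grid[grid$recording == rec_name, ]
    if (!is.null(done)) {
      sub <- sub[!(sub$cell_id %in% done$cell_id), ]
      if (nrow(sub) == 0) next
    }
    rec <- if (by_path) {
      read_recording(recordings[match(rec_name, rec_names)])
    } else {
      recordings[[rec_name]]
    }
    x <- highpass_filter(rec$data, rec$sampling_rate, cutoff = 1)
    if (notch) x <- notch_filter(x, rec$sampling_rate, freq = 50)
    rec$data <- x
    segs_all <- subsegment(segment_trials(rec))
    for (mont_name in unique(sub$montage)) {
      mont <- montages[[mont_name]]
      if (is.null(mont)) stop("unknown montage: ", mont_name)
      segs <- apply_montage(segs_all, mont)
      for (kind in unique(sub$feature_kind[sub$montage == mont_name])) {
        ft <- if (kind == "FFT") {
          build_fft_features(segs)
        } else {
          build_ffdtf_features(segs, mont)
        }
        kept <- attr(ft, "kept") %||% seq_along(segs$condition)
        cells <- sub[sub$montage == mont_name & sub$feature_kind == kind, ]
        for (ci in seq_len(nrow(cells))) {
          cell <- cells[ci, ]
          pair <- comparisons[[cell$comparison]]
          out <- tryCatch(
            nested_classify(ft, segs$condition[kept], segs$trial_id[kept],
              pair = pair, params = params, seed = cell$seed
            ),
            error = function(e) e
          )
          if (inherits(out, "error")) {
            message(sprintf(
              "cell %d (%s %s %s %s) failed: %s",
              cell$cell_id, rec_name, cell$comparison, mont_name, kind,
              conditionMessage(out)
            ))
            results[[length(results) + 1]] <- tibble::tibble(
              cell_id = cell$cell_id, recording = rec_name,
              group = rec$profile, session = rec$session,
              comparison = cell$comparison, montage = mont_name,
              feature_kind = kind, h0 = NA_integer_, n = NA_integer_,
              accuracy = NA_real_, sensitivity = NA_real_,
              specificity = NA_real_, n_features = NA_real_,
              seed = cell$seed
            )
            next
          }
          if (verbose) {
            message(sprintf(
              "cell %d: %s %s %s %s -> %.1f%%",
              cell$cell_id, rec_name, cell$comparison, mont_name, kind,
              100 * out$accuracy
            ))
          }
          results[[length(results) + 1]] <- tibble::tibble(
            cell_id = cell$cell_id, recording = rec_name,
            group = rec$profile, session = rec$session,
            comparison = cell$comparison, montage = mont_name,
            feature_kind = kind, h0 = out$h0, n = out$n,
            accuracy = out$accuracy, sensitivity = out$sensitivity,
            specificity = out$specificity, n_features = out$n_features,
            seed = cell$seed
          )
          feat_union <- sort(unique(unlist(
            lapply(out$selection, function(s) s$consensus)
          )))
          im <- ft$index_map[feat_union, , drop = FALSE]
          sels[[length(sels) + 1]] <- dplyr::bind_cols(
            tibble::tibble(
              cell_id = cell$cell_id, recording = rec_name,
              group = rec$profile, comparison = cell$comparison,
              montage = mont_name, feature_kind = kind
            )[rep(1, nrow(im)), ],
            im
          )
        }
      }
    }
  }
  list(
    results = dplyr::bind_rows(c(list(done), results)),
    selections = dplyr::bind_rows(sels)
  )
}

#' Summarise a results table
#'
#' Pure function of the results (and optionally selections) table:
#' group-wise mean accuracies per montage, comparison and feature kind;
#' counts of recordings strictly above an accuracy threshold; within-class
#' (sensitivity/specificity) accuracy distributions in long format; and the
#' proportion of recordings in which each feature was selected. Patients'
#' repeat sessions count as separate recordings; pass
#' `first_sessions_only = TRUE` for the sensitivity variant restricted to
#' each subject's first session.
#'
#' @param results results tibble from [run_experiment()].
#' @param selections optional selections tibble from [run_experiment()].
#' @param threshold accuracy threshold for the counts table (default 0.75,
#'   strict `>`).
#' @param first_sessions_only restrict to session 1 (default FALSE).
#' @return list with `mean_accuracy`, `counts_above_threshold`,
#'   `within_class`, `selection_heatmap` (NULL without selections).
#' @export
summarize_results <- function(results, selections = NULL, threshold = 0.75,
                              first_sessions_only = FALSE) {
  stopifnot(nrow(results) > 0)
  if (first_sessions_only) results <- dplyr::filter(results, .data$session == 1L)
  grp <- dplyr::group_by(
    results, .data$group, .data$montage,
    .data$comparison, .data$feature_kind
  )
  mean_acc <- dplyr::summarise(grp,
    mean_accuracy = mean(.data$accuracy, na.rm = TRUE),
    n_recordings = dplyr::n_distinct(.data$recording),
    .groups = "drop"
  )
  counts <- dplyr::summarise(grp,
    n_above = sum(.data$accuracy > threshold, na.rm = TRUE),
    n_recordings = dplyr::n_distinct(.data$recording),
    .groups = "drop"
  )
  within <- dplyr::bind_rows(
    dplyr::transmute(results,
      group = .data$group, montage = .data$montage,
      comparison = .data$comparison, feature_kind = .data$feature_kind,
      recording = .data$recording,
      condition = vapply(strsplit(.data$comparison, "-"), `[`, "", 1),
      class_accuracy = .data$sensitivity
    ),
    dplyr::transmute(results,
      group = .data$group, montage = .data$montage,
      comparison = .data$comparison, feature_kind = .data$feature_kind,
      recording = .data$recording,
      condition = vapply(strsplit(.data$comparison, "-"), `[`, "", 2),
      class_accuracy = .data$specificity
    )
  )
  heat <- NULL
  if (!is.null(selections) && nrow(selections) > 0) {
    n_rec <- dplyr::summarise(
      dplyr::group_by(results, .data$group),
      total = dplyr::n_distinct(.data$recording), .groups = "drop"
    )
    heat <- dplyr::summarise(
      dplyr::group_by(
        selections, .data$group, .data$comparison, .data$montage,
        .data$feature_kind, .data$feature, dplyr::across(dplyr::any_of(
          c("channel", "source", "sink", "band")
        ))
      ),
      n_selected = dplyr::n_distinct(.data$recording), .groups = "drop"
    )
    heat <- dplyr::mutate(
      dplyr::left_join(heat, n_rec, by = "group"),
      proportion = .data$n_selected / .data$total
    )
  }
  list(
    mean_accuracy = mean_acc,
    counts_above_threshold = counts,
    within_class = within,
    selection_heatmap = heat
  )
}
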