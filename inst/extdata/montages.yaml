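# Montage definitions: channel label sets and MVAR model order per spatial
# configuration. The HD label sets are synthetic approximations of a
# 256-channel geodesic net layout (HD-whole keeps every recorded channel
# except the face/neck exclusion list below, leaving 197 of 256). Edit or
# replace this file to match a real sensor layout.
LD-SM:
  model_order: 50
  channels:
  - C3
  - C4
LD-whole:
  model_order: 12
  channels:
  - Fp1
  - Fp2
  - F7
  - F3
  - Fz
  - F4
  - F8
  - T3
  - C3
  - Cz
  - C4
  - T4
  - T5
  - P3
  - Pz
  - P4
  - T6
  - O1
  - O2
HD-SM:
  model_order: 9
  channels:
  - FT7
  - FC5
  - FC3
  - FC1
  - FCz
  - FC2
  - FC4
  - FC6
  - FT8
  - T7
  - C5
  - C3
  - C1
  - Cz
  - C2
  - C4
  - C6
  - T8
  - TP7
  - CP5
  - CP3
  - CP1
  - CPz
  - CP2
  - CP4
  - CP6
  - TP8
HD-whole:
  model_order: 1
  exclude:
  - E198
  - E199
  - E200
  - E201
  - E202
  - E203
  - E204
  - E205
  - E206
  - E207
  - E208
  - E209
  - E210
  - E211
  - E212
  - E213
  - E214
  - E215
  - E216
  - E217
  - E218
  - E219
  - E220
  - E221
  - E222
  - E223
  - E224
  - E225
  - E226
  - E227
  - E228
  - E229
  - E230
  - E231
  - E232
  - E233
  - E234
  - E235
  - E236
  - E237
  - E238
  - E239
  - E240
  - E241
  - E242
  - E243
  - E244
  - E245
  - E246
  - E247
  - E248
  - E249
  - E250
  - E251
  - E252
  - E253
  - E254
  - E255
  - E256
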