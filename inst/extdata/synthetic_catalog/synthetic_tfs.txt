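# synthetic stand-in TF identifiers (generated, not curated)
TFX0001
TFX0002
TFX0003
TFX0004
TFX0005
TFX0006
TFX0007
TFX0008
TFX0009
TFX0010
TFX0011
TFX0012
TFX0013
TFX0014
TFX0015
TFX0016
TFX0017
TFX0018
TFX0019
TFX0020
TFX0021
TFX0022
TFX0023
TFX0024
TFX0025
TFX0026
TFX0027
TFX0028
TFX0029
TFX0030
TFX0031
TFX0032
TFX0033
TFX0034
TFX0035
TFX0036
TFX0037
TFX0038
TFX0039
TFX0040
TFX0041
TFX0042
TFX0043
TFX0044
TFX0045
TFX0046
TFX0047
TFX0048
TFX0049
TFX0050
TFX0051
TFX0052
TFX0053
TFX0054
TFX0055
TFX0056
TFX0057
TFX0058
TFX0059
TFX0060
TFX0061
TFX0062
TFX0063
TFX0064
TFX0065
TFX0066
TFX0067
TFX0068
TFX0069
TFX0070
TFX0071
TFX0072
TFX0073
TFX0074
TFX0075
TFX0076
TFX0077
TFX0078
TFX0079
TFX0080
TFX0081
TFX0082
TFX0083
TFX0084
TFX0085
TFX0086
TFX0087
TFX0088
TFX0089
TFX0090
TFX0091
TFX0092
TFX0093
TFX0094
TFX0095
TFX0096
TFX0097
TFX0098
TFX0099
TFX0100
TFX0101
TFX0102
TFX0103
TFX0104
TFX0105
TFX0106
TFX0107
TFX0108
TFX0109
TFX0110
TFX0111
TFX0112
TFX0113
TFX0114
TFX0115
TFX0116
TFX0117
TFX0118
TFX0119
TFX0120
TFX0121
TFX0122
TFX0123
TFX0124
TFX0125
TFX0126
TFX0127
TFX0128
TFX0129
TFX0130
TFX0131
TFX0132
TFX0133
TFX0134
TFX0135
TFX0136
TFX0137
TFX0138
TFX0139
TFX0140
TFX0141
TFX0142
TFX0143
TFX0144
TFX0145
TFX0146
TFX0147
TFX0148
TFX0149
TFX0150
TFX0151
TFX0152
TFX0153
TFX0154
TFX0155
TFX0156
TFX0157
TFX0158
TFX0159
TFX0160
TFX0161
TFX0162
TFX0163
TFX0164
TFX0165
TFX0166
TFX0167
TFX0168
TFX0169
TFX0170
TFX0171
TFX0172
TFX0173
TFX0174
TFX0175
TFX0176
TFX0177
TFX0178
TFX0179
TFX0180
TFX0181
TFX0182
TFX0183
TFX0184
TFX0185
TFX0186
TFX0187
TFX0188
TFX0189
TFX0190
TFX0191
TFX0192
TFX0193
TFX0194
TFX0195
TFX0196
TFX0197
TFX0198
TFX0199
TFX0200
TFX0201
TFX0202
TFX0203
TFX0204
TFX0205
TFX0206
TFX0207
TFX0208
TFX0209
TFX0210
TFX0211
TFX0212
TFX0213
TFX0214
TFX0215
TFX0216
TFX0217
TFX0218
TFX0219
TFX0220
TFX0221
TFX0222
TFX0223
TFX0224
TFX0225
TFX0226
TFX0227
TFX0228
TFX0229
TFX0230
TFX0231
TFX0232
TFX0233
TFX0234
TFX0235
TFX0236
TFX0237
TFX0238
TFX0239
TFX0240
TFX0241
TFX0242
TFX0243
TFX0244
TFX0245
TFX0246
TFX0247
TFX0248
TFX0249
TFX0250
TFX0251
TFX0252
TFX0253
TFX0254
TFX0255
TFX0256
TFX0257
TFX0258
TFX0259
TFX0260
TFX0261
TFX0262
TFX0263
TFX0264
TFX0265
TFX0266
TFX0267
TFX0268
TFX0269
TFX0270
TFX0271
TFX0272
TFX0273
TFX0274
TFX0275
TFX0276
TFX0277
TFX0278
TFX0279
TFX0280
TFX0281
TFX0282
TFX0283
TFX0284
TFX0285
TFX0286
TFX0287
TFX0288
TFX0289
TFX0290
TFX0291
TFX0292
TFX0293
TFX0294
TFX0295
TFX0296
TFX0297
TFX0298
TFX0299
TFX0300
TFX0301
TFX0302
TFX0303
TFX0304
TFX0305
TFX0306
TFX0307
TFX0308
TFX0309
TFX0310
TFX0311
TFX0312
TFX0313
TFX0314
TFX0315
TFX0316
TFX0317
TFX0318
TFX0319
TFX0320
TFX0321
TFX0322
TFX0323
TFX0324
TFX0325
TFX0326
TFX0327
TFX0328
TFX0329
TFX0330
TFX0331
TFX0332
TFX0333
TFX0334
TFX0335
TFX0336
TFX0337
TFX0338
TFX0339
TFX0340
TFX0341
TFX0342
TFX0343
TFX0344
TFX0345
TFX0346
TFX0347
TFX0348
TFX0349
TFX0350
TFX0351
TFX0352
TFX0353
TFX0354
TFX0355
TFX0356
TFX0357
TFX0358
TFX0359
TFX0360
TFX0361
TFX0362
TFX0363
TFX0364
TFX0365
TFX0366
TFX0367
TFX0368
TFX0369
TFX0370
TFX0371
TFX0372
TFX0373
TFX0374
TFX0375
TFX0376
TFX0377
TFX0378
TFX0379
TFX0380
TFX0381
TFX0382
TFX0383
TFX0384
TFX0385
TFX0386
TFX0387
TFX0388
TFX0389
TFX0390
TFX0391
TFX0392
TFX0393
TFX0394
TFX0395
TFX0396
TFX0397
TFX0398
TFX0399
TFX0400
TFX0401
TFX0402
TFX0403
TFX0404
TFX0405
TFX0406
TFX0407
TFX0408
TFX0409
TFX0410
TFX0411
TFX0412
TFX0413
TFX0414
TFX0415
TFX0416
TFX0417
TFX0418
TFX0419
DUALTF001
DUALTF002
DUALTF003
DUALTF004
DUALTF005
DUALTF006
DUALTF007
DUALTF008
DUALTF009
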