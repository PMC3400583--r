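# synthetic stand-in gene identifiers (generated, not curated)
GBMG0001
GBMG0002
GBMG0003
GBMG0004
GBMG0005
GBMG0006
GBMG0007
GBMG0008
GBMG0009
GBMG0010
GBMG0011
GBMG0012
GBMG0013
GBMG0014
GBMG0015
GBMG0016
GBMG0017
GBMG0018
GBMG0019
GBMG0020
GBMG0021
GBMG0022
GBMG0023
GBMG0024
GBMG0025
GBMG0026
GBMG0027
GBMG0028
GBMG0029
GBMG0030
GBMG0031
GBMG0032
GBMG0033
GBMG0034
GBMG0035
GBMG0036
GBMG0037
GBMG0038
GBMG0039
GBMG0040
GBMG0041
GBMG0042
GBMG0043
GBMG0044
GBMG0045
GBMG0046
GBMG0047
GBMG0048
GBMG0049
GBMG0050
GBMG0051
GBMG0052
GBMG0053
GBMG0054
GBMG0055
GBMG0056
GBMG0057
GBMG0058
GBMG0059
GBMG0060
GBMG0061
GBMG0062
GBMG0063
GBMG0064
GBMG0065
GBMG0066
GBMG0067
GBMG0068
GBMG0069
GBMG0070
GBMG0071
GBMG0072
GBMG0073
GBMG0074
GBMG0075
GBMG0076
GBMG0077
GBMG0078
GBMG0079
GBMG0080
GBMG0081
GBMG0082
GBMG0083
GBMG0084
GBMG0085
GBMG0086
GBMG0087
GBMG0088
GBMG0089
GBMG0090
GBMG0091
GBMG0092
GBMG0093
GBMG0094
GBMG0095
GBMG0096
GBMG0097
GBMG0098
GBMG0099
GBMG0100
GBMG0101
GBMG0102
GBMG0103
GBMG0104
GBMG0105
GBMG0106
GBMG0107
GBMG0108
GBMG0109
GBMG0110
GBMG0111
GBMG0112
GBMG0113
GBMG0114
GBMG0115
GBMG0116
GBMG0117
GBMG0118
GBMG0119
GBMG0120
GBMG0121
GBMG0122
GBMG0123
GBMG0124
GBMG0125
GBMG0126
GBMG0127
GBMG0128
GBMG0129
GBMG0130
GBMG0131
GBMG0132
GBMG0133
GBMG0134
GBMG0135
GBMG0136
GBMG0137
GBMG0138
GBMG0139
GBMG0140
GBMG0141
GBMG0142
GBMG0143
GBMG0144
GBMG0145
GBMG0146
GBMG0147
GBMG0148
GBMG0149
GBMG0150
GBMG0151
GBMG0152
GBMG0153
GBMG0154
GBMG0155
GBMG0156
GBMG0157
GBMG0158
GBMG0159
GBMG0160
GBMG0161
GBMG0162
GBMG0163
GBMG0164
GBMG0165
GBMG0166
GBMG0167
GBMG0168
GBMG0169
GBMG0170
GBMG0171
GBMG0172
GBMG0173
GBMG0174
GBMG0175
GBMG0176
GBMG0177
GBMG0178
GBMG0179
GBMG0180
GBMG0181
GBMG0182
GBMG0183
GBMG0184
GBMG0185
GBMG0186
GBMG0187
GBMG0188
GBMG0189
GBMG0190
GBMG0191
GBMG0192
GBMG0193
GBMG0194
GBMG0195
GBMG0196
GBMG0197
GBMG0198
GBMG0199
GBMG0200
GBMG0201
GBMG0202
GBMG0203
GBMG0204
GBMG0205
GBMG0206
GBMG0207
GBMG0208
GBMG0209
GBMG0210
GBMG0211
GBMG0212
GBMG0213
GBMG0214
GBMG0215
GBMG0216
GBMG0217
GBMG0218
GBMG0219
GBMG0220
GBMG0221
GBMG0222
GBMG0223
GBMG0224
GBMG0225
GBMG0226
GBMG0227
GBMG0228
GBMG0229
GBMG0230
GBMG0231
GBMG0232
GBMG0233
GBMG0234
GBMG0235
GBMG0236
GBMG0237
GBMG0238
GBMG0239
GBMG0240
GBMG0241
GBMG0242
GBMG0243
GBMG0244
GBMG0245
GBMG0246
GBMG0247
GBMG0248
GBMG0249
GBMG0250
GBMG0251
GBMG0252
GBMG0253
GBMG0254
GBMG0255
GBMG0256
GBMG0257
GBMG0258
GBMG0259
GBMG0260
GBMG0261
GBMG0262
GBMG0263
GBMG0264
GBMG0265
GBMG0266
GBMG0267
GBMG0268
GBMG0269
GBMG0270
GBMG0271
GBMG0272
GBMG0273
GBMG0274
GBMG0275
GBMG0276
GBMG0277
GBMG0278
GBMG0279
GBMG0280
GBMG0281
GBMG0282
GBMG0283
GBMG0284
GBMG0285
GBMG0286
GBMG0287
GBMG0288
GBMG0289
GBMG0290
GBMG0291
GBMG0292
GBMG0293
GBMG0294
GBMG0295
GBMG0296
GBMG0297
GBMG0298
GBMG0299
GBMG0300
GBMG0301
GBMG0302
GBMG0303
GBMG0304
GBMG0305
GBMG0306
GBMG0307
GBMG0308
GBMG0309
GBMG0310
GBMG0311
GBMG0312
GBMG0313
GBMG0314
GBMG0315
GBMG0316
GBMG0317
GBMG0318
GBMG0319
GBMG0320
GBMG0321
GBMG0322
GBMG0323
GBMG0324
GBMG0325
GBMG0326
GBMG0327
GBMG0328
GBMG0329
GBMG0330
GBMG0331
GBMG0332
GBMG0333
GBMG0334
GBMG0335
GBMG0336
GBMG0337
GBMG0338
GBMG0339
GBMG0340
GBMG0341
GBMG0342
GBMG0343
GBMG0344
GBMG0345
GBMG0346
GBMG0347
GBMG0348
GBMG0349
GBMG0350
GBMG0351
GBMG0352
GBMG0353
GBMG0354
GBMG0355
GBMG0356
GBMG0357
GBMG0358
GBMG0359
GBMG0360
GBMG0361
GBMG0362
GBMG0363
GBMG0364
GBMG0365
GBMG0366
GBMG0367
GBMG0368
GBMG0369
GBMG0370
GBMG0371
GBMG0372
GBMG0373
GBMG0374
GBMG0375
GBMG0376
GBMG0377
GBMG0378
GBMG0379
GBMG0380
GBMG0381
GBMG0382
GBMG0383
GBMG0384
GBMG0385
GBMG0386
GBMG0387
GBMG0388
GBMG0389
GBMG0390
GBMG0391
GBMG0392
GBMG0393
GBMG0394
GBMG0395
GBMG0396
GBMG0397
GBMG0398
GBMG0399
GBMG0400
GBMG0401
GBMG0402
GBMG0403
GBMG0404
GBMG0405
GBMG0406
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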