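type,record,n_t,ac,n_normal,se_normal,pp_normal,n_pvc,se_pvc,pp_pvc,n_apc,se_apc,pp_apc
I,115,1952,100.00,1952,100.00,100.00,0,NA,NA,0,NA,NA
I,122,2474,100.00,2474,100.00,100.00,0,NA,NA,0,NA,NA
II,106,2027,93.73,1507,99.54,96.21,520,98.07,96.15,0,NA,NA
II,119,1987,100.00,1543,100.00,100.00,444,100.00,100.00,0,NA,NA
II,123,1517,99.01,1514,100.00,99.08,3,100.00,75.00,0,NA,NA
II,221,2427,99.56,2031,99.46,99.93,396,99.24,95.96,0,NA,NA
II,230,2255,99.65,2254,100.00,99.65,1,100.00,100.00,0,NA,NA
III,101,1864,99.30,1859,100.00,99.31,0,NA,NA,5,100.00,100.00
III,103,2083,99.95,2081,100.00,100.00,0,NA,NA,2,100.00,66.67
III,112,2537,99.40,2535,100.00,99.41,0,NA,NA,2,100.00,25.00
III,117,1534,100.00,1533,100.00,100.00,0,NA,NA,1,100.00,100.00
III,220,2046,100.00,1952,100.00,100.00,0,NA,NA,94,100.00,100.00
IV,100,2271,99.87,2237,100.00,100.00,1,100.00,100.00,33,100.00,89.63
IV,116,2411,99.34,2301,99.52,100.00,109,91.74,86.96,1,100.00,50.00
IV,215,3361,98.51,3194,98.62,100.00,164,93.29,90.00,3,100.00,100.00
IV,228,2053,99.10,1688,98.93,99.52,362,96.69,100.00,3,75.00,100.00
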