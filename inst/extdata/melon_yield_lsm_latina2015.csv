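parent_a,parent_b,lsm
Vedrantais,Ita1,8.08
Vedrantais,Ogen,10.29
Vedrantais,Top Mark,9.48
Vedrantais,Magyar Kincs,9.42
Vedrantais,Hale's Best Jumbo,9.39
Vedrantais,PI414723,12.44
Vedrantais,PI161375,8.62
Ita1,Ogen,9.45
Ita1,Top Mark,8.56
Ita1,Magyar Kincs,11.27
Ita1,Hale's Best Jumbo,9.34
Ita1,PI414723,12.91
Ita1,PI161375,13.42
Ogen,Top Mark,9.56
Ogen,Magyar Kincs,8.28
Ogen,Hale's Best Jumbo,9.34
Ogen,PI414723,13.48
Ogen,PI161375,9.93
Top Mark,Magyar Kincs,10.71
Top Mark,Hale's Best Jumbo,10.73
Top Mark,PI414723,7.56
Top Mark,PI161375,12.14
Magyar Kincs,Hale's Best Jumbo,9.01
Magyar Kincs,PI414723,11.12
Magyar Kincs,PI161375,13.09
Hale's Best Jumbo,PI414723,10.54
Hale's Best Jumbo,PI161375,11.88
PI414723,PI161375,14.11
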