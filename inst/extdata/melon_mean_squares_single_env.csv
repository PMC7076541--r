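trait,env,term,df,meansq
yield,LT2014,Entries,27,10.93
yield,LT2014,GCA,7,32.12
yield,LT2014,SCA,20,3.52
yield,LT2014,Error,54,2.83
yield,PG2014,Entries,27,8.2
yield,PG2014,GCA,7,28.11
yield,PG2014,SCA,20,1.23
yield,PG2014,Error,54,0.72
yield,LT2015,Entries,27,9.98
yield,LT2015,GCA,7,17.6
yield,LT2015,SCA,20,7.32
yield,LT2015,Error,54,4.04
yield,PG2015,Entries,27,12.04
yield,PG2015,GCA,7,32.5
yield,PG2015,SCA,20,4.87
yield,PG2015,Error,54,2.01
yield,LT2016,Entries,27,23.03
yield,LT2016,GCA,7,65.67
yield,LT2016,SCA,20,8.11
yield,LT2016,Error,54,4.41
yield,PG2016,Entries,27,23.73
yield,PG2016,GCA,7,79.26
yield,PG2016,SCA,20,4.3
yield,PG2016,Error,54,3.04
TSS,LT2014,Entries,27,128.38
TSS,LT2014,GCA,7,12.53
TSS,LT2014,SCA,20,1.08
TSS,LT2014,Error,2730,3.44
TSS,PG2014,Entries,27,70.66
TSS,PG2014,GCA,7,14.52
TSS,PG2014,SCA,20,1.11
TSS,PG2014,Error,1438,3.08
TSS,LT2015,Entries,27,171.44
TSS,LT2015,GCA,7,20.47
TSS,LT2015,SCA,20,1.42
TSS,LT2015,Error,2415,2.98
TSS,PG2015,Entries,27,179.98
TSS,PG2015,GCA,7,31.61
TSS,PG2015,SCA,20,0.92
TSS,PG2015,Error,1706,3.51
TSS,LT2016,Entries,27,291.74
TSS,LT2016,GCA,7,30.37
TSS,LT2016,SCA,20,1.76
TSS,LT2016,Error,2880,5.71
DTR,LT2014,Entries,27,77.08
DTR,LT2014,GCA,7,49.42
DTR,LT2014,SCA,20,3.49
DTR,LT2014,Error,385,1.17
DTR,PG2014,Entries,27,139.21
DTR,PG2014,GCA,7,77.24
DTR,PG2014,SCA,20,10.55
DTR,PG2014,Error,390,5.56
DTR,LT2015,Entries,27,162.67
DTR,LT2015,GCA,7,111.41
DTR,LT2015,SCA,20,4.93
DTR,LT2015,Error,390,1.32
DTR,PG2015,Entries,27,143.21
DTR,PG2015,GCA,7,86.72
DTR,PG2015,SCA,20,8.32
DTR,PG2015,Error,390,6.58
DTR,LT2016,Entries,27,144.14
DTR,LT2016,GCA,7,98.26
DTR,LT2016,SCA,20,4.58
DTR,LT2016,Error,390,2.39
DTR,PG2016,Entries,27,269.13
DTR,PG2016,GCA,7,128.15
DTR,PG2016,SCA,20,27.81
DTR,PG2016,Error,390,10.55
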