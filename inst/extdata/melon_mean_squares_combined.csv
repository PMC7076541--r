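trait,method,n_env,term,df,meansq
yield,method2,6,Environments,5,329.46
yield,method2,6,Entries,35,28.03
yield,method2,6,GCA,7,82.95
yield,method2,6,SCA,28,14.31
yield,method2,6,Env x Entries,175,3.29
yield,method2,6,Env x GCA,35,6.55
yield,method2,6,Env x SCA,140,2.48
yield,method2,6,Error,420,1.35
yield,method4,6,Environments,5,763.43
yield,method4,6,Entries,27,62.32
yield,method4,6,GCA,7,216.06
yield,method4,6,SCA,20,8.51
yield,method4,6,Env x Entries,135,5.12
yield,method4,6,Env x GCA,35,7.84
yield,method4,6,Env x SCA,100,4.17
yield,method4,6,Error,324,2.86
TSS,method4,5,Environments,4,6504.65
TSS,method4,5,Entries,27,634.81
TSS,method4,5,GCA,7,86.73
TSS,method4,5,SCA,20,3.64
TSS,method4,5,Env x Entries,108,54.38
TSS,method4,5,Env x GCA,28,5.670
TSS,method4,5,Env x SCA,80,0.66
TSS,method4,5,Error,11169,3.89
DTR,method4,6,Environments,5,3696.62
DTR,method4,6,Entries,27,712.42
DTR,method4,6,GCA,7,456.55
DTR,method4,6,SCA,20,32.16
DTR,method4,6,Env x Entries,135,44.62
DTR,method4,6,Env x GCA,35,18.93
DTR,method4,6,Env x SCA,100,5.50
DTR,method4,6,Error,2335,4.61
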