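"tissue","time_min","pct_dose"
"blood",5,1.63738561100146
"blood",30,1.46101245483226
"blood",60,0.749587072654474
"blood",120,1.46975408493188
"blood",240,0.780776583321959
"blood",480,0.363861473092856
"blood",1440,0.344389659733374
"gi",5,3.35973613377252
"gi",30,6.76821042031097
"gi",60,7.24627524866261
"gi",120,13.6777470806368
"gi",240,15.1157133071955
"gi",480,16.8943436483838
"gi",1440,17.5819251333412
"heart",5,1.30862704853297
"heart",30,0.976668067029623
"heart",60,0.962894185514206
"heart",120,1.02484653271705
"heart",240,0.884709622514811
"heart",480,0.67584695977918
"heart",1440,0.352332792866698
"kidney",5,6.45114341450478
"kidney",30,4.44472082355134
"kidney",60,1.48180838268342
"kidney",120,2.75587546729013
"kidney",240,1.53117689225739
"kidney",480,1.11644469525673
"kidney",1440,0.353881766718101
"liver",5,2.03760493702453
"liver",30,1.69782196069933
"liver",60,2.07458958668977
"liver",120,0.812185604044887
"liver",240,0.830827921849082
"liver",480,0.512553595007693
"liver",1440,0.0372183746426381
"lung",5,0.292231414437336
"lung",30,0.183578344257223
"lung",60,0.212381705865696
"lung",120,0.324135170208694
"lung",240,0.215121963692322
"lung",480,0.0932370664634123
"lung",1440,0.0449726072584698
"thyroid",5,0.439502728068591
"thyroid",30,0.168378296180498
"thyroid",60,0.0453199045422454
"thyroid",120,0.0340352689158863
"thyroid",240,0.0745311624143034
"thyroid",480,0.073641676194837
"thyroid",1440,0.0220598771649714
"urine",5,4.67521634700649
"urine",30,6.16952581704728
"urine",60,7.31730562169416
"urine",120,9.98480242581459
"urine",240,12.6197906230253
"urine",480,19.8585983866121
"urine",1440,35.7153100302927
"urine",2880,41.8375040584837
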