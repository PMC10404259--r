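trait,genotype,masi,rank_masi,mean,rank_mean,ssi
pod_yield,ABHAYA,1.33,7,158.5,25,32
pod_yield,AK 265,8.46,30,137.1,30,60
pod_yield,ANANTHA,2.51,19,223.7,4,23
pod_yield,CSMG 84-1,3.67,22,221.9,5,27
pod_yield,Dh 3-30,5.21,26,149.5,29,55
pod_yield,DHARANI,1.14,5,155.9,27,32
pod_yield,DRG 17,1.87,13,180.4,17,30
pod_yield,DSG 41,3.06,21,185.1,14,35
pod_yield,GG 2,4.40,25,163.6,24,49
pod_yield,Girnar 2,2.04,15,182.1,15,30
pod_yield,GPBD 5,1.37,9,194.8,12,21
pod_yield,ICGS 1,1.81,12,204.9,7,19
pod_yield,ICGS 44,1.94,14,191.7,13,27
pod_yield,ICGS 76,3.03,20,171.2,22,42
pod_yield,ICGV 86031,6.03,28,265.4,1,29
pod_yield,ICGV 86325,1.24,6,202.7,8,14
pod_yield,ICGV 91114,1.35,8,200.0,10,18
pod_yield,K 6,4.11,23,198.0,11,34
pod_yield,K 9,1.43,10,168.7,23,33
pod_yield,KADIRI 5,0.91,4,211.0,6,10
pod_yield,KADIRI HARITHANDRA,2.46,18,156.6,26,44
pod_yield,MUTANT 3,0.64,3,171.6,21,24
pod_yield,R 2001-2,6.38,29,250.8,2,31
pod_yield,R 2001-3,5.53,27,235.5,3,30
pod_yield,R 8808,2.42,17,179.4,18,35
pod_yield,SPANISH IMPROVED,4.27,24,181.8,16,40
pod_yield,TAG 24,0.62,2,174.4,19,21
pod_yield,TDG 39,2.30,16,202.3,9,25
pod_yield,TG 72,0.47,1,154.7,28,29
pod_yield,TMV 2,1.54,11,173.9,20,31
rue,ABHAYA,0.41,5,32.00,28,33
rue,AK 265,3.09,30,28.00,30,60
rue,ANANTHA,1.17,18,45.28,7,25
rue,CSMG 84-1,1.31,20,47.56,5,25
rue,Dh 3-30,2.28,28,34.52,25,53
rue,DHARANI,0.48,6,31.83,29,35
rue,DRG 17,0.73,11,38.33,15,26
rue,DSG 41,1.45,22,41.89,10,32
rue,GG 2,1.73,25,35.41,21,46
rue,Girnar 2,0.90,14,36.72,17,31
rue,GPBD 5,1.41,21,48.70,3,24
rue,ICGS 1,0.65,10,42.28,9,19
rue,ICGS 44,0.81,13,39.37,14,27
rue,ICGS 76,1.18,19,36.59,18,37
rue,ICGV 86031,2.32,29,55.48,1,30
rue,ICGV 86325,0.76,12,40.49,13,25
rue,ICGV 91114,0.51,7,40.75,12,19
rue,K 6,1.46,23,42.78,8,31
rue,K 9,0.51,9,35.15,24,33
rue,KADIRI 5,0.28,4,45.86,6,10
rue,KADIRI HARITHANDRA,0.91,16,32.80,26,42
rue,MUTANT 3,0.19,1,35.29,23,24
rue,R 2001-2,2.24,27,54.65,2,29
rue,R 2001-3,2.20,26,48.29,4,30
rue,R 8808,0.90,15,37.68,16,31
rue,SPANISH IMPROVED,1.48,24,36.21,19,43
rue,TAG 24,0.21,3,35.42,20,23
rue,TDG 39,0.98,17,41.39,11,28
rue,TG 72,0.21,2,32.25,27,29
rue,TMV 2,0.51,8,35.31,22,30
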