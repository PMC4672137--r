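dataset,voe,rvd,asd,rmsd,msd,printed_score
1,8.28,0.43,1.33,1.98,16.8,76.5
2,5.43,1.32,0.95,1.69,17.52,80.3
3,6.47,1.74,1.08,2.43,22.75,74.96
4,6.73,0.88,0.42,0.95,15.14,85.08
5,5.8,0.34,0.57,1.09,13.16,85.77
6,7.15,0.54,0.96,1.65,17.1,79.96
7,5.12,0.45,0.76,1.28,13.35,84.65
8,6.28,0.9,0.92,1.49,17.84,80.7
9,4.16,3.53,0.72,1.26,16.7,81.5
10,5.25,0.73,0.93,2.23,19.8,79.07
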