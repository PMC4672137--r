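dataset,voe,rvd,asd,rmsd,msd,printed_score
1,5.1,2.5,0.7,1.4,16.1,81.73
2,5.4,1.4,0.7,1.7,21.4,80.44
3,4.9,0.1,0.7,1.3,16.2,84.69
4,5.7,2.3,0.8,1.8,19.6,78.94
5,6.1,0.1,1.2,2.5,28.3,74.74
6,5.2,0.6,0.7,1.8,21.4,81.17
7,4.09,0.5,0.6,1.5,15.9,84.92
8,5.9,1.8,0.9,1.8,19.2,78.92
9,4.8,3.7,0.5,0.8,16.1,83.35
10,6.4,1.04,0.8,1.7,13.4,81.65
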