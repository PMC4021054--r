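id,cadaver,side,age,sex,height_m,weight_kg,microct_bvtv_percent,mr_bvtv_percent
C1-R,1,right,72,male,1.75,59,44.98,4.32
C2-R,2,right,53,male,1.70,70,28.39,1.23
C3-R,3,right,57,female,1.64,57,15.28,2.03
C4-R,4,right,76,male,1.73,96,32.16,4.25
C5-R,5,right,78,female,1.68,48,12.13,0.09
C1-L,1,left,72,male,1.75,59,33.74,5.03
C2-L,2,left,53,male,1.70,70,31.79,0.62
C3-L,3,left,57,female,1.64,57,15.55,1.17
C4-L,4,left,76,male,1.73,96,38.11,3.02
C5-L,5,left,78,female,1.68,48,14.26,0.20
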