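id,group,age,sex,regular_contact_lens,dry_gritty,full_rate_per_min,partial_rate_per_min,eye_score,duration_s,open_close_pct
1,control,58,M,FALSE,FALSE,10,1,0,65,42.3
2,control,20,F,TRUE,FALSE,29,0,1,63,7.8
3,control,21,F,FALSE,FALSE,25,5,0,61,9.1
4,control,22,F,FALSE,FALSE,15,1,0,61,14.3
5,control,53,F,FALSE,FALSE,23,8,4,62,3.7
6,control,47,F,TRUE,TRUE,21,6,6,62,2.4
7,control,56,F,TRUE,FALSE,31,3,5,60,7.3
8,control,80,F,FALSE,TRUE,22,1,3,60,4.0
9,control,65,M,FALSE,TRUE,28,0,2,62,7.9
10,control,29,M,FALSE,FALSE,18,0,0,58,18.4
DED1,ded,48,F,TRUE,FALSE,39,1,4,62,2.6
DED2,ded,80,M,FALSE,TRUE,16,14,5,61,60
DED3,ded,83,F,FALSE,TRUE,35,3,6,62,6.8
DED4,ded,21,F,TRUE,FALSE,36,8,7,61,3.4
DED5,ded,60,M,TRUE,FALSE,40,14,7,61,19.3
DED6,ded,51,F,TRUE,TRUE,64,0,7,61,3.0
DED7,ded,28,F,TRUE,TRUE,13,6,6,61,9.9
DED8,ded,44,F,TRUE,TRUE,23,1,4,61,9.8
DED9,ded,60,M,FALSE,TRUE,55,0,6,61,3.9
DED10,ded,19,M,TRUE,TRUE,53,11,9,61,7.2
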