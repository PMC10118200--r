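age,sex,tc,hdl,sbp,treated_htn,diabetes,smoker,exp_frs,exp_pce
61,F,180,47,124,0,0,1,0.10484180203720028,0.07153259257908273
55,F,213,50,120,0,0,0,0.05347667912647547,0.02052229820249485
55,M,213,50,120,0,0,0,0.10232506159577903,0.05384421997908706
45,M,220,42,135,1,0,1,0.2115881522965558,0.10043415842724102
68,F,250,60,150,1,1,0,0.3827527712546577,0.26402318575890016
40,F,190,70,110,0,0,0,0.01402900779985694,0.0024079909638270447
74,M,175,38,160,1,1,1,0.9003356058879322,0.6525279403249769
52,M,205,55,128,0,0,0,0.08631441088446112,0.039715110030574374
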