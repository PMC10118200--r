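scr,cys,bun,ua,alb,age,sex,black_race,exp_cre_2021,exp_cre_2009,exp_cys_2012,exp_crecys_2021,exp_mdrd4,exp_mdrd6
0.4,0.5,8.0,5.0,3.2,20,F,FALSE,145.21814165021624,149.93788434998783,144.6472539247823,158.1885133734041,203.49588654902968,184.41688529894807
0.6,0.5,9.7,5.0,3.57,20,M,FALSE,141.7254200396817,144.73634125545524,155.20091622830716,154.05665581077054,171.76806237130836,161.73925792513893
0.7,0.7,11.4,5.0,3.94,20,F,FALSE,126.89622572879938,124.72452554951049,122.29038248614943,125.53078840891536,106.68165062640725,106.06870110587366
0.8,0.7,13.1,5.0,4.31,20,M,TRUE,129.93203916295357,149.0428701442621,131.21285674479552,132.58363830459086,149.37080942830096,144.4488236356252
0.9,0.8,14.8,5.0,4.68,20,F,FALSE,93.85887442682,92.04415117201773,114.40745420693152,104.86830927882444,79.82464741739234,83.37803226671919
1.0,0.8,16.5,5.0,5.05,20,M,FALSE,110.49921783688585,107.8656777164139,122.7547791919866,117.89638686330393,95.26403215719627,99.0525442293796
1.3,1.0,18.2,5.0,3.42,20,F,FALSE,60.37182859227512,59.00894878958614,85.06635507030317,72.17237841990442,52.22064555341772,50.45741248023961
1.8,1.0,19.9,5.0,3.79,35,M,FALSE,49.71839311532917,47.69771180923743,85.94725061811197,67.88602256987835,43.15267920689674,44.1165521962493
2.6,1.6,21.6,5.0,4.16,35,F,FALSE,23.93774419436587,22.972662945892807,42.91178338628379,32.38541412456277,20.946761960505793,23.649811797508402
3.5,1.6,23.3,5.0,4.53,35,M,FALSE,22.38527514551738,21.34733858028453,46.04268603678518,32.799728158260976,20.032618134553367,23.392750900130224
0.4,0.5,25.0,5.0,4.9,35,F,TRUE,132.28352554156734,156.39884517636403,136.2072640515405,149.18290030311218,220.1514401499577,186.04934703481646
0.6,0.5,26.7,5.0,3.27,35,M,FALSE,129.10190151631565,130.26157275552785,146.14513310251127,145.2862678505522,153.32242964369104,119.99488190308604
0.7,0.7,28.4,5.0,3.64,35,F,FALSE,115.59354724258125,112.25109546324043,115.15488864321289,118.38436744122554,95.22544323217754,80.25732905480513
0.8,0.7,30.1,5.0,4.01,35,M,FALSE,118.35896001672118,115.73547454955603,123.55674747125846,125.03570122268498,110.00853741647751,94.1181235751139
0.9,0.8,31.8,5.0,4.38,50,F,FALSE,77.88343795839066,74.55446393833982,101.44589417600663,93.2679581536428,66.27583181617624,61.009387797136256
1.0,0.8,33.5,5.0,4.75,50,M,FALSE,91.6914786098333,87.36967723743611,108.84752593992127,104.85489231256896,79.09465531827084,73.29675645530817
1.3,1.0,35.2,5.0,5.12,50,F,FALSE,50.09612138772333,47.79641605201736,75.42893524046042,64.18879465691694,43.35711880985249,43.64303687447085
1.8,1.0,36.9,5.0,3.49,50,M,TRUE,45.289963435829016,49.75304991703626,80.93233394899187,64.02129662291706,48.648033195162355,42.878796187630655
2.6,1.6,8.6,5.0,3.86,50,F,FALSE,21.805603346516776,20.675216602532753,40.407933452075476,30.54172457651994,19.48371640271922,25.36415676986873
3.5,1.6,10.3,5.0,4.23,50,M,FALSE,20.39141310318958,19.212437412002156,43.35615177261317,30.93245186679721,18.633421780107117,24.69583632985409
0.4,0.5,12.0,5.0,4.6,50,F,FALSE,120.50099891689698,121.44757107782979,128.2597372367227,140.68997342628853,168.95607545481784,164.41711542070303
0.6,0.5,13.7,5.0,4.97,65,M,FALSE,107.12785550071611,105.51003626948368,129.58791723693054,129.21495200381227,135.21662580253147,137.69732770150355
0.7,0.7,15.4,5.0,3.34,65,F,FALSE,95.91871754308336,90.92180374517373,102.10864954673062,105.28889332235327,83.98029664888878,77.70959743684304
0.8,0.7,17.1,5.0,3.71,65,M,FALSE,98.21343773378835,93.74410164928213,109.55863685271525,111.20446805661987,97.01765927852749,90.64929761856482
0.9,0.8,18.8,5.0,4.08,65,F,TRUE,70.9463407075524,77.76708410451951,95.52665066259237,87.95824808003451,76.16006508279095,73.49056480139012
1.0,0.8,20.5,5.0,4.45,65,M,FALSE,83.5244957330708,78.63202475185071,102.49640629033516,98.88554239861445,74.99229374081585,74.52124519249172
1.3,1.0,22.2,5.0,4.82,65,F,FALSE,45.634047356757975,43.01639984131265,71.0277493741187,60.53455051616756,41.10833755403984,44.21343842670644
1.8,1.0,23.9,5.0,5.19,65,M,FALSE,41.25597509277324,38.63447367098104,76.21003151729474,60.376588082775285,38.05679110522585,42.381675304632346
2.6,1.6,25.6,5.0,3.56,80,F,FALSE,18.09413724333381,16.746633772852935,35.82999874672511,27.1632517901015,17.71068843496938,18.90538782594052
3.5,1.6,27.3,5.0,3.93,80,M,FALSE,16.920652064120308,15.56180326465089,38.44420466386814,27.51075750283473,16.937771049613108,18.818018609250178
0.4,0.5,29.0,5.0,4.3,80,F,FALSE,99.99088664104512,98.37081925389806,113.7288109498959,125.12709172483846,153.58098782210953,127.51493040108387
0.6,0.5,30.7,5.0,4.67,80,M,TRUE,97.58595068291326,110.05656041234431,122.02662119087542,121.85879297666564,157.11833138686148,133.89576513085305
0.7,0.7,32.4,5.0,5.04,80,F,FALSE,87.37521343984197,81.82891076894191,96.15073507022808,99.29483589277146,80.51402691006837,75.25077502309536
0.8,0.7,34.1,5.0,3.41,80,M,FALSE,89.46554233062918,84.36895676281516,103.1660247534636,104.87363916361677,93.01327503713414,75.66402497852302
0.9,0.8,35.8,5.0,3.78,80,F,FALSE,64.62713243964909,60.388064014468405,89.95278774891248,82.9508178206721,60.24469786990481,52.526404183219434
1.0,0.8,37.5,5.0,4.15,20,M,FALSE,110.49921783688585,107.8656777164139,122.7547791919866,117.89638686330393,95.26403215719627,80.93665034739358
1.3,1.0,9.2,5.0,4.52,20,F,FALSE,60.37182859227512,59.00894878958614,85.06635507030317,72.17237841990442,52.22064555341772,61.91657167679145
1.8,1.0,10.9,5.0,4.89,20,M,FALSE,54.57983240531543,52.99791909071037,91.27291316556133,71.98404755064537,48.344212329042634,58.48058756188008
2.6,1.6,12.6,5.0,3.26,20,F,TRUE,26.27836469411108,29.58394246568316,45.570782667599154,34.34040030685577,28.441745181079426,31.23273782235931
3.5,1.6,14.3,5.0,3.63,20,M,FALSE,24.574096008193614,23.719471646872847,48.89568955750982,34.77972492735378,22.442665493842537,26.140293020875774
0.4,0.5,16.0,5.0,4.0,20,F,FALSE,145.21814165021624,149.93788434998783,144.6472539247823,158.1885133734041,203.49588654902968,175.97175591760865
0.6,0.5,17.7,5.0,4.37,20,M,FALSE,141.7254200396817,144.73634125545524,155.20091622830716,154.05665581077054,171.76806237130836,155.71691460769205
0.7,0.7,19.4,5.0,4.74,35,F,FALSE,115.59354724258125,112.25109546324043,115.15488864321289,118.38436744122554,95.22544323217754,93.13004199506024
0.8,0.7,21.1,5.0,5.11,35,M,FALSE,118.35896001672118,115.73547454955603,123.55674747125846,125.03570122268498,110.00853741647751,107.98899084004681
0.9,0.8,22.8,5.0,3.48,35,F,FALSE,85.49884106387417,82.8390146566779,107.73191956157979,98.89819554198483,71.25252924509867,63.89347822690658
1.0,0.8,24.5,5.0,3.85,35,M,TRUE,100.6570249346469,112.51370860772296,115.59218837079376,111.1845895283726,103.06111946319656,90.84830644928786
1.3,1.0,26.2,5.0,4.22,35,F,FALSE,54.9944947568158,53.107591426643005,80.10283757608036,68.06363183298808,46.61283444243716,45.949443200995454
1.8,1.0,27.9,5.0,4.59,35,M,FALSE,49.71839311532917,47.69771180923743,85.94725061811197,67.88602256987835,43.15267920689674,44.269339027879035
2.6,1.6,29.6,5.0,4.96,35,F,FALSE,23.93774419436587,22.972662945892807,42.91178338628379,32.38541412456277,20.946761960505793,23.705915380009415
3.5,1.6,31.3,5.0,3.33,50,M,FALSE,20.39141310318958,19.212437412002156,43.35615177261317,30.93245186679721,18.633421780107117,18.94630648839461
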