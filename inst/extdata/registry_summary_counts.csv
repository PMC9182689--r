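cancer_type,category,level,value
Esophagus,total,n,56445
Kidney,total,n,196685
Liver,total,n,91436
Mesothelioma,total,n,10092
Ovary,total,n,85530
Pancreas,total,n,147680
Overall,total,n,587868
Esophagus,sex,Female,11303
Esophagus,sex,Male,45142
Kidney,sex,Female,70726
Kidney,sex,Male,125959
Liver,sex,Female,22093
Liver,sex,Male,69343
Mesothelioma,sex,Female,2017
Mesothelioma,sex,Male,8075
Ovary,sex,Female,85530
Ovary,sex,Male,0
Pancreas,sex,Female,70213
Pancreas,sex,Male,77467
Overall,sex,Female,261882
Overall,sex,Male,325986
Esophagus,age,25-29,0
Esophagus,age,30-34,0
Esophagus,age,35-39,212
Esophagus,age,40-44,752
Esophagus,age,45-49,2314
Esophagus,age,50-54,4575
Esophagus,age,55-59,7097
Esophagus,age,60-64,8812
Esophagus,age,65-69,9593
Esophagus,age,70-74,8893
Esophagus,age,75-79,8089
Esophagus,age,80-84,6108
Kidney,age,25-29,592
Kidney,age,30-34,1990
Kidney,age,35-39,4100
Kidney,age,40-44,8098
Kidney,age,45-49,13549
Kidney,age,50-54,20016
Kidney,age,55-59,25790
Kidney,age,60-64,28823
Kidney,age,65-69,29798
Kidney,age,70-74,26132
Kidney,age,75-79,22219
Kidney,age,80-84,15578
Liver,age,25-29,0
Liver,age,30-34,0
Liver,age,35-39,316
Liver,age,40-44,1409
Liver,age,45-49,4900
Liver,age,50-54,10873
Liver,age,55-59,16476
Liver,age,60-64,16431
Liver,age,65-69,13412
Liver,age,70-74,11126
Liver,age,75-79,9551
Liver,age,80-84,6942
Mesothelioma,age,25-29,0
Mesothelioma,age,30-34,0
Mesothelioma,age,35-39,0
Mesothelioma,age,40-44,0
Mesothelioma,age,45-49,104
Mesothelioma,age,50-54,383
Mesothelioma,age,55-59,639
Mesothelioma,age,60-64,1142
Mesothelioma,age,65-69,1533
Mesothelioma,age,70-74,1936
Mesothelioma,age,75-79,2298
Mesothelioma,age,80-84,2057
Ovary,age,25-29,782
Ovary,age,30-34,1436
Ovary,age,35-39,2165
Ovary,age,40-44,4429
Ovary,age,45-49,7350
Ovary,age,50-54,9967
Ovary,age,55-59,11187
Ovary,age,60-64,11320
Ovary,age,65-69,10645
Ovary,age,70-74,9778
Ovary,age,75-79,8913
Ovary,age,80-84,7558
Pancreas,age,25-29,0
Pancreas,age,30-34,201
Pancreas,age,35-39,713
Pancreas,age,40-44,2406
Pancreas,age,45-49,5490
Pancreas,age,50-54,10214
Pancreas,age,55-59,15604
Pancreas,age,60-64,20251
Pancreas,age,65-69,23201
Pancreas,age,70-74,24112
Pancreas,age,75-79,24190
Pancreas,age,80-84,21298
Overall,age,25-29,1374
Overall,age,30-34,3627
Overall,age,35-39,7506
Overall,age,40-44,17094
Overall,age,45-49,33707
Overall,age,50-54,56028
Overall,age,55-59,76793
Overall,age,60-64,86779
Overall,age,65-69,88182
Overall,age,70-74,81977
Overall,age,75-79,75260
Overall,age,80-84,59541
Esophagus,ancestry,African American,6668
Esophagus,ancestry,Asian/Pacific Islander,1934
Esophagus,ancestry,Caucasian,44149
Esophagus,ancestry,Hispanic,3694
Kidney,ancestry,African American,22642
Kidney,ancestry,Asian/Pacific Islander,9021
Kidney,ancestry,Caucasian,139920
Kidney,ancestry,Hispanic,25102
Liver,ancestry,African American,12026
Liver,ancestry,Asian/Pacific Islander,14454
Liver,ancestry,Caucasian,47688
Liver,ancestry,Hispanic,17268
Mesothelioma,ancestry,African American,0
Mesothelioma,ancestry,Asian/Pacific Islander,0
Mesothelioma,ancestry,Caucasian,9414
Mesothelioma,ancestry,Hispanic,678
Ovary,ancestry,African American,6885
Ovary,ancestry,Asian/Pacific Islander,6183
Ovary,ancestry,Caucasian,62426
Ovary,ancestry,Hispanic,10036
Pancreas,ancestry,African American,18091
Pancreas,ancestry,Asian/Pacific Islander,9716
Pancreas,ancestry,Caucasian,105221
Pancreas,ancestry,Hispanic,14652
Overall,ancestry,African American,66312
Overall,ancestry,Asian/Pacific Islander,41308
Overall,ancestry,Caucasian,408818
Overall,ancestry,Hispanic,71430
Esophagus,survival,mean,25.3
Esophagus,survival,sd,36.6
Esophagus,survival,median,10.0
Esophagus,survival,min,0
Esophagus,survival,max,199
Kidney,survival,mean,77.3
Kidney,survival,sd,53.1
Kidney,survival,median,75.1
Kidney,survival,min,0
Kidney,survival,max,203
Liver,survival,mean,22.5
Liver,survival,sd,32.7
Liver,survival,median,8.13
Liver,survival,min,0
Liver,survival,max,195
Mesothelioma,survival,mean,16.1
Mesothelioma,survival,sd,22.1
Mesothelioma,survival,median,9.00
Mesothelioma,survival,min,0
Mesothelioma,survival,max,185
Ovary,survival,mean,56.6
Ovary,survival,sd,51.3
Ovary,survival,median,43.8
Ovary,survival,min,0
Ovary,survival,max,198
Pancreas,survival,mean,13.5
Pancreas,survival,sd,23.6
Pancreas,survival,median,5.00
Pancreas,survival,min,0
Pancreas,survival,max,193
Overall,survival,mean,43.7
Overall,survival,sd,50.2
Overall,survival,median,20.0
Overall,survival,min,0
Overall,survival,max,203
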