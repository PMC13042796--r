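dimension,disease,stratum,cases_thousands,ui_low,ui_high,paf_percent,asir,asir_low,asir_high
sex,asthma,female,182.1,152.3,213.8,,6.7,3.9,10.2
sex,asthma,male,124.2,104.5,145.1,,4.7,2.8,7.1
sex,asthma,total,306.3,256.7,359.0,,5.7,3.4,8.7
sex,type2_diabetes,female,101.9,93.1,111.1,,3.7,2.9,4.7
sex,type2_diabetes,male,90.4,82.7,98.7,,3.4,2.6,4.3
sex,type2_diabetes,total,192.3,175.8,209.7,,3.6,2.7,4.5
sex,ischemic_heart_disease,female,432.9,356.6,521.7,,13.4,8.8,19.4
sex,ischemic_heart_disease,male,359.9,297.1,433.0,,13.3,8.9,18.9
sex,ischemic_heart_disease,total,792.8,653.7,954.7,,13.5,8.9,19.3
sex,stroke,female,172.5,154.8,191.7,,5.3,4.2,6.8
sex,stroke,male,140.7,125.5,158.0,,5.2,4.1,6.6
sex,stroke,total,313.3,280.2,349.8,,5.3,4.2,6.7
sex,testicular_cancer,male,2.1,1.9,2.3,,0.08,0.07,0.09
sex,testicular_cancer,total,2.1,1.9,2.3,,0.04,0.03,0.05
sex,uterine_cancer,female,36.6,32.6,40.6,,1.2,1.1,1.4
sex,uterine_cancer,total,36.6,32.6,40.6,,0.6,0.5,0.7
sex,depression,female,6613.3,5634.6,7843.8,,248.0,184.7,329.8
sex,depression,male,2953.0,2508.9,3491.8,,113.4,85.0,150.2
sex,depression,total,9566.3,8143.5,11335.5,,181.3,135.3,240.7
sex,total,female,7539.2,6423.9,8922.7,3.4,278.5,205.5,372.3
sex,total,male,3670.4,3120.5,4329.0,2.3,140.1,103.4,187.2
sex,total,total,11209.6,9544.4,13251.6,2.9,210.1,155.1,280.7
development,asthma,more developed,105.4,86.9,124.9,,,,
development,asthma,less developed,200.9,169.9,234.1,,,,
development,type2_diabetes,more developed,51.9,48.0,56.2,,,,
development,type2_diabetes,less developed,140.3,127.8,153.6,,,,
development,ischemic_heart_disease,more developed,181.9,153.4,216.3,,,,
development,ischemic_heart_disease,less developed,610.8,500.2,738.3,,,,
development,stroke,more developed,73.5,66.0,81.9,,,,
development,stroke,less developed,239.8,214.3,267.9,,,,
development,testicular_cancer,more developed,1.0,0.9,1.1,,,,
development,testicular_cancer,less developed,1.1,1.0,1.2,,,,
development,uterine_cancer,more developed,24.9,23.0,26.3,,,,
development,uterine_cancer,less developed,11.7,9.6,14.3,,,,
development,depression,more developed,2427.4,2089.0,2818.7,,,,
development,depression,less developed,7138.9,6054.4,8516.8,,,,
development,total,more developed,2866.0,2467.3,3325.3,3.4,268.5,199.6,356.6
development,total,less developed,8343.6,7077.1,9926.3,2.8,200.4,147.5,268.5
age_band,asthma,20-49,162.4,91.6,253.3,,,,
age_band,asthma,50-69,97.3,60.7,142.6,,,,
age_band,asthma,70+,46.6,28.6,67.2,,,,
age_band,type2_diabetes,20-49,86.5,63.9,112.4,,,,
age_band,type2_diabetes,50-69,92.6,73.7,113.0,,,,
age_band,type2_diabetes,70+,13.2,9.7,17.4,,,,
age_band,ischemic_heart_disease,20-49,91.6,55.1,137.6,,,,
age_band,ischemic_heart_disease,50-69,337.1,218.2,494.0,,,,
age_band,ischemic_heart_disease,70+,364.0,253.4,504.4,,,,
age_band,stroke,20-49,44.0,33.5,57.2,,,,
age_band,stroke,50-69,113.0,86.4,145.9,,,,
age_band,stroke,70+,156.2,124.9,192.7,,,,
age_band,testicular_cancer,20-49,1.8,1.6,2.0,,,,
age_band,testicular_cancer,50-69,0.3,0.2,0.3,,,,
age_band,testicular_cancer,70+,0.08,0.07,0.1,,,,
age_band,uterine_cancer,20-49,4.2,3.6,5.0,,,,
age_band,uterine_cancer,50-69,21.6,19.2,24.4,,,,
age_band,uterine_cancer,70+,10.7,9.1,12.0,,,,
age_band,depression,20-49,5834.1,4271.2,7891.9,,,,
age_band,depression,50-69,2749.3,2145.3,3497.0,,,,
age_band,depression,70+,982.9,737.1,1281.5,,,,
age_band,total,20-49,6224.7,4520.4,8459.3,,,,
age_band,total,50-69,3411.2,2603.7,4417.1,,,,
age_band,total,70+,1573.8,1162.9,2075.3,,,,
region,total,East Asia and Pacific,2319.9,1993.4,2714.9,2.7,120.8,89.6,160.3
country,total,China,1483.5,1259.7,1749.9,2.8,118.8,87.7,157.6
region,total,Europe and Central Asia,1701.8,1465.3,1975.6,2.9,227.2,166.6,305.7
region,total,Latin America and Caribbean,1215.8,1045.0,1445.0,3.4,268.6,200.6,356.4
region,total,Middle East and North Africa,947.8,770.5,1156.4,3.2,324.5,231.2,449.7
region,total,North America,1067.6,924.3,1231.2,4.4,405.5,309.0,526.3
country,total,USA,985.6,854.2,1136.2,4.3,417.9,318.7,540.6
region,total,South Asia,2274.2,1934.7,2706.5,2.3,198.3,147.7,262.5
country,total,India,1692,1438.7,2005.3,2.3,191.6,142.7,252.9
region,total,Sub-Saharan Africa,1682.6,1411.2,2022.0,3.7,338.6,247.2,456.1
world,total,world,11209.6,9544.4,13251.6,2.9,210.1,155.1,280.7
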