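name,mean,std,min,max,class_shifted
baseline value,133.303857,9.840844,106.0,160.0,1
accelerations,0.003178,0.003866,0.0,0.019,1
fetal_movement,0.009481,0.046666,0.0,0.481,0
uterine_contractions,0.004366,0.002946,0.0,0.015,1
light_decelerations,0.001889,0.002960,0.0,0.015,0
severe_decelerations,0.000003,0.000057,0.0,0.001,0
prolongued_decelerations,0.000159,0.000590,0.0,0.005,1
abnormal_short_term_variability,46.990122,17.192814,12.0,87.0,1
mean_value_of_short_term_variability,1.332785,0.883241,0.2,7.0,1
percentage_of_time_with_abnormal_long_term_variability,9.846660,18.396880,0.0,91.0,1
mean_value_of_long_term_variability,8.187629,5.628247,0.0,50.7,0
histogram_width,70.445908,38.955693,3.0,180.0,0
histogram_min,93.579492,29.560212,50.0,159.0,0
histogram_max,164.025400,17.944183,122.0,238.0,0
histogram_number_of_peaks,4.068203,2.949386,0.0,18.0,0
histogram_number_of_zeroes,0.323612,0.706059,0.0,10.0,0
histogram_mode,137.452023,16.381289,60.0,187.0,0
histogram_mean,134.610536,15.593596,73.0,182.0,0
histogram_median,138.090310,14.466589,77.0,186.0,0
histogram_variance,18.80809,28.977636,0.0,269.0,1
histogram_tendency,0.320320,0.610829,-1.0,1.0,0
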