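dataset,bird,majority_rank,minority_rank,pr_score,pr_rank,kl_score,kl_rank,hpa_score,hpa_rank
synthetic,E,1,8,0.99,1,0.61,1,19.13,6
synthetic,B,2,2,0.99,2,2.55,2,14.52,2
synthetic,D,3,6,0.99,3,3.50,3,31.54,11
synthetic,F,4,4,0.98,4,30.45,11,18.21,5
synthetic,G,5,3,0.96,5,19.27,8,31.06,10
synthetic,I,6,1,0.95,6,15.84,5,16.56,3
synthetic,C,7,4,0.89,8,15.45,4,13.67,1
synthetic,H,8,7,0.44,10,24.06,10,20.39,7
synthetic,A,9,8,0.20,11,21.67,9,18.08,4
synthetic,J,10,10,0.90,7,15.84,5,21.88,8
synthetic,K,11,11,0.76,9,15.84,5,23.93,9
two_point,C,1,,0.96,1,14.10,2,17.33,1
two_point,E,2,,0.94,2,9.42,1,24.31,3
two_point,A,3,,0.70,4,15.31,3,27.21,4
two_point,B,4,,0.53,5,15.89,4,31.05,5
two_point,D,5,,0.81,3,20.57,5,24.27,2
three_point,H,1,,0.63,7,11.80,4,29.63,9
three_point,F,2,,0.87,2,10.44,1,24.46,7
three_point,C,3,,0.86,3,14.84,6,19.02,3
three_point,E,4,,0.71,6,18.84,10,22.26,5
three_point,I,5,,0.85,4,14.18,5,17.08,1
three_point,A,6,,0.84,5,16.61,8,27.78,8
three_point,J,7,,0.89,1,11.60,3,20.09,4
three_point,B,8,,0.34,9,18.01,9,17.64,2
three_point,G,9,,0.05,10,15.03,7,32.60,10
three_point,D,10,,0.50,8,10.57,2,24.44,6
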