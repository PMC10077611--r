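# Published-cohort summary: per-angle mean and SD of ACEA (deg), LCEA (deg),
# and acetabular coverage (fraction) for 142 normal adult hips
# (76 men, 66 women), by APP tilt angle. synthetic: no (transcribed summary).
app_tilt_deg,measure,group,n,mean,sd
-30,acea,overall,142,9.61,8.76
-30,acea,men,76,11.71,9.50
-30,acea,women,66,7.19,7.17
-30,lcea,overall,142,26.95,7.67
-30,lcea,men,76,30.22,7.26
-30,lcea,women,66,23.18,6.32
-30,coverage,overall,142,0.65,0.09
-30,coverage,men,76,0.67,0.09
-30,coverage,women,66,0.63,0.08
-25,acea,overall,142,13.62,8.83
-25,acea,men,76,15.86,9.49
-25,acea,women,66,11.06,7.25
-25,lcea,overall,142,28.61,7.38
-25,lcea,men,76,31.67,7.01
-25,lcea,women,66,25.09,6.15
-25,coverage,overall,142,0.69,0.09
-25,coverage,men,76,0.71,0.09
-25,coverage,women,66,0.67,0.08
-20,acea,overall,142,17.53,9.02
-20,acea,men,76,19.95,9.54
-20,acea,women,66,14.75,7.53
-20,lcea,overall,142,30.27,7.19
-20,lcea,men,76,33.11,6.97
-20,lcea,women,66,27.00,5.97
-20,coverage,overall,142,0.73,0.10
-20,coverage,men,76,0.75,0.09
-20,coverage,women,66,0.72,0.09
-15,acea,overall,142,21.70,9.10
-15,acea,men,76,24.16,9.70
-15,acea,women,66,18.87,7.48
-15,lcea,overall,142,31.66,7.00
-15,lcea,men,76,34.44,6.82
-15,lcea,women,66,28.45,5.75
-15,coverage,overall,142,0.76,0.08
-15,coverage,men,76,0.78,0.09
-15,coverage,women,66,0.75,0.08
-10,acea,overall,142,25.69,9.14
-10,acea,men,76,28.26,9.83
-10,acea,women,66,22.73,7.29
-10,lcea,overall,142,33.11,6.94
-10,lcea,men,76,35.90,6.73
-10,lcea,women,66,29.89,5.71
-10,coverage,overall,142,0.79,0.08
-10,coverage,men,76,0.81,0.08
-10,coverage,women,66,0.78,0.07
-5,acea,overall,142,29.74,9.16
-5,acea,men,76,32.42,9.81
-5,acea,women,66,26.65,7.27
-5,lcea,overall,142,33.89,6.77
-5,lcea,men,76,36.66,6.52
-5,lcea,women,66,30.70,5.57
-5,coverage,overall,142,0.81,0.07
-5,coverage,men,76,0.83,0.07
-5,coverage,women,66,0.80,0.07
0,acea,overall,142,33.84,9.29
0,acea,men,76,36.75,9.83
0,acea,women,66,30.48,7.36
0,lcea,overall,142,34.74,6.65
0,lcea,men,76,37.41,6.50
0,lcea,women,66,31.67,5.40
0,coverage,overall,142,0.84,0.07
0,coverage,men,76,0.85,0.07
0,coverage,women,66,0.82,0.06
5,acea,overall,142,37.46,9.32
5,acea,men,76,40.42,9.80
5,acea,women,66,34.05,7.45
5,lcea,overall,142,34.95,6.55
5,lcea,men,76,37.42,6.42
5,lcea,women,66,32.11,5.48
5,coverage,overall,142,0.84,0.06
5,coverage,men,76,0.86,0.06
5,coverage,women,66,0.83,0.06
10,acea,overall,142,41.15,9.52
10,acea,men,76,44.29,9.86
10,acea,women,66,37.55,7.71
10,lcea,overall,142,35.13,6.61
10,lcea,men,76,37.47,6.54
10,lcea,women,66,32.43,5.62
10,coverage,overall,142,0.85,0.06
10,coverage,men,76,0.87,0.07
10,coverage,women,66,0.84,0.06
15,acea,overall,142,44.68,9.81
15,acea,men,76,48.05,10.06
15,acea,women,66,40.80,7.96
15,lcea,overall,142,34.76,6.67
15,lcea,men,76,37.00,6.66
15,lcea,women,66,32.18,5.71
15,coverage,overall,142,0.84,0.06
15,coverage,men,76,0.86,0.06
15,coverage,women,66,0.84,0.06
20,acea,overall,142,48.16,10.12
20,acea,men,76,51.67,10.30
20,acea,women,66,44.12,8.30
20,lcea,overall,142,34.36,6.89
20,lcea,men,76,36.51,6.93
20,lcea,women,66,31.89,6.00
20,coverage,overall,142,0.84,0.06
20,coverage,men,76,0.85,0.07
20,coverage,women,66,0.83,0.06
25,acea,overall,142,51.56,10.61
25,acea,men,76,55.31,10.81
25,acea,women,66,47.24,8.60
25,lcea,overall,142,33.70,7.04
25,lcea,men,76,35.77,7.14
25,lcea,women,66,31.30,6.14
25,coverage,overall,142,0.84,0.06
25,coverage,men,76,0.85,0.07
25,coverage,women,66,0.83,0.06
30,acea,overall,142,54.91,11.05
30,acea,men,76,58.77,11.20
30,acea,women,66,50.46,9.08
30,lcea,overall,142,32.96,7.14
30,lcea,men,76,34.81,7.44
30,lcea,women,66,30.84,6.19
30,coverage,overall,142,0.83,0.07
30,coverage,men,76,0.84,0.07
30,coverage,women,66,0.82,0.06
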