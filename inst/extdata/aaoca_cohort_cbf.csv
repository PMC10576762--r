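patient_id,anomalous_side,lca_rest_insilico,lca_rest_invivo,lca_rest_reldiff,rca_rest_insilico,rca_rest_invivo,rca_rest_reldiff,lca_hyperemia_insilico,lca_hyperemia_invivo,lca_hyperemia_reldiff,rca_hyperemia_insilico,rca_hyperemia_invivo,rca_hyperemia_reldiff
1,right,1.65,1.72,-0.04,0.76,0.75,0.01,7.54,7.75,-0.03,6.84,6.25,0.09
2,left,1.03,1.02,0.01,1.72,1.73,-0.01,5.24,5.05,-0.41,5.30,5.53,-0.04
3,right,0.91,0.97,-0.06,2.66,2.67,0.00,3.50,3.47,0.01,4.66,4.77,-0.02
4,right,1.68,1.75,-0.04,1.06,1.03,0.02,7.41,7.23,0.02,4.37,3.53,0.24
5,right,2.06,2.23,-0.08,1.04,1.23,-0.16,6.02,6.20,-0.03,3.21,4.03,-0.20
6,right,1.60,1.73,-0.07,1.23,1.25,-0.01,8.21,7.25,0.13,4.67,4.58,0.02
7,left,1.04,1.13,-0.08,1.79,1.85,-0.03,5.90,5.65,0.04,5.29,4.13,0.28
8,left,1.05,1.07,-0.01,1.37,1.33,0.03,9.89,8.70,0.14,5.73,5.25,0.09
9,right,2.82,3.22,-0.12,0.87,0.87,0.00,7.25,6.73,0.08,3.93,2.83,0.39
10,right,1.25,1.37,-0.09,0.79,0.83,-0.05,2.98,3.00,-0.01,2.76,2.45,0.13
11,right,1.21,1.18,0.02,0.43,0.43,0.00,5.83,5.62,0.04,2.45,2.33,0.05
12,right,9.76,10.32,-0.05,0.96,1.02,-0.06,13.84,14.22,-0.03,3.30,2.98,0.11
13,right,1.78,1.48,0.20,1.04,1.13,-0.08,4.16,2.85,0.46,2.25,2.32,-0.08
14,right,1.13,1.18,-0.04,0.87,0.90,-0.03,5.61,5.72,-0.02,3.48,3.53,-0.02
15,right,2.45,2.50,-0.02,2.13,2.03,0.05,3.62,3.62,0.00,3.02,2.83,0.07
16,left,3.59,3.43,0.05,4.11,3.98,0.03,7.55,7.13,0.06,8.33,7.45,0.12
17,right,1.77,1.73,0.02,1.96,2.08,-0.06,5.51,5.02,0.10,4.43,3.03,0.46
18,left,1.33,1.78,-0.25,3.67,3.65,0.01,6.79,6.32,0.07,7.31,7.07,0.03
19,right,0.71,0.83,-0.15,0.74,0.97,-0.23,2.08,2.57,-0.19,1.97,2.50,-0.21
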