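formula_id,auc,auc_lo,auc_hi,optimal_cutoff,tp,fp,fn,tn,accuracy_pct,sensitivity_pct,specificity_pct,youden
england_fraser,0.67,0.617,0.719,-31.930,228,200,1,1,53.26,99.56,0.50,0.00
rbc_count,0.84,0.805,0.88,4.545,81,3,148,198,64.88,35.37,98.51,0.34
mentzer,0.91,0.878,0.935,18.227,62,0,167,201,61.16,27.07,100.00,0.27
srivastava,0.92,0.89,0.943,5.915,26,0,203,201,52.79,11.35,100.00,0.11
shine_lal,0.90,0.874,0.934,1820.666,167,13,62,188,82.56,72.93,93.53,0.66
bessman,0.75,0.704,0.801,13.650,131,169,98,32,37.91,57.21,15.92,-0.27
ricerca,0.60,0.551,0.658,2.939,171,130,58,71,56.28,74.67,35.32,0.10
green_king,0.83,0.786,0.866,75.777,84,4,145,197,65.35,36.68,98.01,0.35
das_gupta,0.75,0.7,0.793,0.498,193,124,36,77,62.79,84.28,38.31,0.23
rdw_index,0.87,0.84,0.909,252.550,117,5,112,196,72.79,51.09,97.51,0.49
ti_mchd,0.86,0.825,0.899,0.329,222,145,7,56,64.65,96.94,27.86,0.25
ti_mdhl,0.76,0.718,0.808,1.510,135,39,94,162,69.07,58.95,80.60,0.40
huber_herklotz,0.64,0.587,0.691,22.041,23,8,206,193,50.23,10.04,96.02,0.06
sirdah,0.90,0.867,0.928,40.945,36,0,193,201,55.12,15.72,100.00,0.16
kerman_1,0.92,0.89,0.944,473.980,94,0,135,201,68.60,41.05,100.00,0.41
kerman_2,0.90,0.873,0.932,45.788,228,199,1,2,53.49,99.56,1.00,0.01
ehsani,0.91,0.882,0.938,37.500,63,0,166,201,61.40,27.51,100.00,0.28
keikhaei,0.87,0.839,0.90,25.695,89,3,140,198,66.74,38.86,98.51,0.37
nishad,0.91,0.88,0.939,71.604,81,0,148,201,65.58,35.37,100.00,0.35
wongprachum,0.81,0.763,0.847,127.029,132,187,97,14,33.95,57.64,6.97,-0.35
sehgal,0.91,0.883,0.939,1421.514,103,0,126,201,70.70,44.98,100.00,0.45
sargolzaie,0.89,0.853,0.918,11.274,57,3,172,198,59.30,24.89,98.51,0.23
pornprasert,0.86,0.825,0.899,32.850,23,5,206,196,50.93,10.04,97.51,0.08
sirachainan,0.74,0.688,0.785,166.220,229,201,0,0,53.26,100.00,0.00,0.00
plengsuree,0.60,0.551,0.658,2.939,171,130,58,71,56.28,74.67,35.32,0.10
bordbar,0.70,0.648,0.749,64.880,135,47,94,154,67.21,58.95,76.62,0.36
hisham,0.90,0.873,0.933,81.779,96,0,133,201,69.07,41.92,100.00,0.42
hameed,0.77,0.721,0.811,49.905,229,201,0,0,53.26,100.00,0.00,0.00
chandra,0.52,0.469,0.579,0.590,227,198,2,3,53.49,99.13,1.49,0.01
matos_carvalho,0.68,0.632,0.733,23.169,58,10,171,191,57.91,25.33,95.02,0.20
ravanbakhsh_f1,0.84,0.805,0.88,2.171,83,3,146,198,65.35,36.24,98.51,0.35
ravanbakhsh_f2,0.60,0.544,0.651,-0.295,172,142,57,59,53.72,75.11,29.35,0.04
ravanbakhsh_f3,0.86,0.823,0.895,673.350,138,13,91,188,75.81,60.26,93.53,0.54
ravanbakhsh_f4,0.87,0.839,0.908,13.714,114,8,115,193,71.40,49.78,96.02,0.46
zaghloul_1,0.72,0.67,0.768,153.530,229,201,0,0,53.26,100.00,0.00,0.00
zaghloul_2,0.73,0.678,0.776,139.120,229,201,0,0,53.26,100.00,0.00,0.00
kandhro_1,0.76,0.709,0.805,6.971,186,179,43,22,48.37,81.22,10.95,-0.08
kandhro_2,0.60,0.551,0.658,14.696,176,135,53,66,56.28,76.86,32.84,0.10
merdin_1,0.88,0.843,0.909,0.709,41,2,188,199,55.81,17.90,99.00,0.17
merdin_2,0.83,0.792,0.869,93.715,229,201,0,0,53.26,100.00,0.00,0.00
alparslan,0.92,0.894,0.947,4.381,102,0,127,201,70.47,44.54,100.00,0.45
roth_svm,0.90,0.873,0.933,0.911,167,14,62,187,82.33,72.93,93.03,0.66
cruise,0.86,0.823,0.897,339.503,229,201,0,0,53.26,100.00,0.00,0.00
xs1,0.92,0.888,0.943,3.989,188,22,41,179,85.35,82.10,89.05,0.71
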