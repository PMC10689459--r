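[experiment]
doses = [1.0000000000000001e-09, 3.5938136638046257e-09, 1.2915496650148827e-08, 4.6415888336127821e-08, 1.6681005372000591e-07, 5.9948425031894092e-07, 2.1544346900318865e-06, 7.7426368268112769e-06, 2.782559402207126e-05, 0.0001]
response_columns = ["dose_01", "dose_02", "dose_03", "dose_04", "dose_05", "dose_06", "dose_07", "dose_08", "dose_09", "dose_10"]
control_offset = 2

[fit]
objective = "OLS"
min_n = 5
tol = 1e-10
maxit = 500

[statistic]
dfn = 5
loc = 0.12
scale = 1
k = 4

[classification]
alpha = 0.050000000000000003
fc_lim = 0.45000000000000001
rmse_limit = 0.10000000000000001
intercept_space = "log2"
s0_use_loc = false
fc_mode = "range"

[preprocessing]
median_center = false
impute = false
impute_quantile = 0.0050000000000000001
max_missing = 4

[fdr]
enabled = true
n_decoys = 200

[io]
id_column = "curve_id"
delimiter = "	"
output = "example_results.tsv"
seed = 42

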