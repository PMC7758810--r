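label,pearson,rmse,mape_pct,smape_pct,annual_rate,annual_error_pct
health_services,0.802,56.847,5.457,2.629,15.08,4.14
online,0.633,52.035,4.189,2.149,14.12,2.49
baseline_plus_health_services,0.832,46.096,4.367,2.123,14.91,2.97
baseline_plus_online,0.737,80.478,7.306,3.841,13.37,7.67
health_services_plus_online,0.791,43.239,3.806,1.916,14.31,1.17
all_sources,0.811,44.439,4.006,2.001,14.40,0.55
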