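label,category,pearson,rmse,mape_pct,smape_pct,annual_rate,annual_error_pct
historical,historical_fatalities,0.761,79.790,7.485,3.941,13.35,7.80
poison,health_services,0.702,162.019,17.103,9.409,11.95,17.47
lifeline,health_services,0.491,83.871,7.256,3.419,15.27,5.46
ed_visits,health_services,0.511,54.353,4.894,2.441,14.38,0.69
google,online,0.721,85.040,7.846,4.135,13.28,8.29
youtube,online,0.580,155.892,13.683,7.715,12.65,12.64
reddit,online,0.507,210.986,22.255,12.596,11.19,22.72
twitter,online,0.389,72.640,6.466,3.355,13.75,5.04
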