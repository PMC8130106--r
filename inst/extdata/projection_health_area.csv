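year,traditional_eur,alternative_eur,difference_eur,difference_pct
2015,376073.09,379053.01,-2979.92,-0.79
2016,414545.37,183882.33,230663.04,55.64
2017,456953.36,208362.92,248590.44,54.40
2018,503699.69,224542.51,279157.18,55.42
2019,555228.16,247632.86,307595.30,55.40
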