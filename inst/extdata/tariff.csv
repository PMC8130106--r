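start_date,end_date,daily_rate_eur
2013-01-01,2014-01-31,1.10
2014-02-01,2014-07-06,0.86
2014-07-07,,0.65
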