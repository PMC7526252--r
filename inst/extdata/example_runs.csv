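run_id,sample_id,role,raw_d2h
run1,USGS42,reference,-71.9
run1,USGS42,reference,-72.3
run1,USGS43,reference,-44.0
run1,USGS43,reference,-44.3
run1,goat,qc,-29.8
run1,bat_001,sample,-24.6
run1,bat_002,sample,-31.2
run2,USGS42,reference,-70.1
run2,USGS43,reference,-42.4
run2,goat,qc,-28.1
run2,bat_003,sample,-27.9
run2,bat_004,sample,-35.5
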