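year,age_category,count
2022,0-4,3237500
2022,5-9,3542074
2022,10-14,3436207
2022,0-17,12097402
2023,0-17,12059255
2030,0-17,11643646
2040,0-17,10807953
2050,0-17,11121906
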