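AT03G09601	AT03G09601
AT03G04189	AT03G04189
AT01G00938	AT01G00938
AT01G02604	AT01G02604
AT04G06696	AT04G06696
AT01G01592	AT01G01592
AT04G08231	AT04G08231
AT05G06579	AT05G06579
AT01G00391	AT01G00391
AT04G08031	AT04G08031
AT04G07800	AT04G07800
AT03G04101	AT03G04101
AT02G01843	AT02G01843
AT03G08478	AT03G08478
AT02G02427	AT02G02427
AT05G01025	AT05G01025
probe_multi	AT04G08710,AT05G03756
AT04G08710	AT04G08710
probe_nomatch	
probe_wide	AT03G09601,AT03G04189,AT01G00938,AT01G02604
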