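disease,group,cases,py,ir_published
AMI,Total,18349,6868414,26.7
AMI,Female,6791,3561742,19.1
AMI,Male,11558,3306672,35.0
AMI,30-59,4895,4256183,11.5
AMI,60-69,4470,1321559,33.8
AMI,70-79,4595,859414,53.5
AMI,80+,4389,431258,101.8
AMI,Low,4572,1367521,33.4
AMI,Medium,11017,4124208,26.7
AMI,High,2760,1376685,20.0
stroke,Total,28006,6817459,41.1
stroke,Female,13391,3506561,38.2
stroke,Male,14615,3310898,44.1
stroke,30-59,5775,4238191,13.6
stroke,60-69,5991,1313460,45.6
stroke,70-79,7676,848137,90.5
stroke,80+,8564,416943,205.4
stroke,Low,6991,1357075,51.5
stroke,Medium,16448,4093957,40.2
stroke,High,4567,1366427,33.4
AF,Total,39040,6790503,57.5
AF,Female,17754,3506072,50.6
AF,Male,21286,3284431,64.8
AF,30-59,4805,4256227,11.3
AF,60-69,8412,1312313,64.1
AF,70-79,12345,831006,148.6
AF,80+,13478,390956,344.7
AF,Low,8600,1351987,63.6
AF,Medium,23295,4077683,57.1
AF,High,7145,1360833,52.5
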