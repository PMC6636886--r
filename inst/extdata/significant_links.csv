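source_table,bct_code,moa_id,frequency,p_display
1,4.1,1,17,.013
1,4.1,2,20,.024
1,1.1,14,15,.003
1,1.2,4,65,.008
1,1.2,11,9,.026
1,1.2,2,18,.038
1,3.1,12,34,<.001
1,3.1,3,5,.037
1,6.1,4,60,.003
1,6.1,2,17,.020
1,6.1,23,3,.044
1,1.4,14,14,.001
1,2.2,16,19,<.001
1,2.2,1,13,.013
1,5.1,1,18,<.001
1,5.1,6,26,<.001
1,5.1,17,19,<.001
1,5.1,26,10,<.001
1,5.1,8,28,.004
1,8.1,2,24,<.001
1,8.1,4,47,.013
1,6.2,16,31,<.001
1,6.2,12,9,.043
1,5.3,6,20,<.001
1,5.3,17,16,<.001
1,5.3,1,13,.002
1,2.3,14,18,<.001
1,9.1,25,2,.007
1,9.1,3,4,.023
1,12.5,11,8,<.001
1,7.1,10,8,<.001
1,7.1,24,6,.002
1,7.1,11,5,.036
1,8.7,4,28,<.001
1,9.2,6,12,<.001
1,9.2,17,9,<.001
1,9.2,22,3,.005
1,9.2,18,5,.023
1,13.2,19,2,<.050
1,13.2,17,7,.014
1,8.2,14,5,.016
1,10.4,7,3,.020
1,15.3,4,23,<.001
1,12.1,11,9,<.001
1,12.1,24,3,.020
1,1.8,9,4,.002
1,6.3,16,13,<.001
1,6.3,8,12,.043
1,15.1,4,27,<.001
1,2.7,16,5,.020
1,2.7,22,2,.027
1,11.2,4,12,.039
1,5.2,17,4,.025
1,1.9,21,1,.039
1,2.4,14,5,.024
1,5.6,6,6,.005
1,5.6,17,5,.006
1,5.6,13,2,.024
1,1.3,9,4,.003
1,3.2,12,4,.023
1,3.2,11,3,.026
1,1.6,9,3,.001
1,1.6,14,3,.019
1,12.3,20,1,.027
1,13.1,19,2,.011
1,12.2,11,3,.004
1,12.2,12,6,<.001
1,10.3,7,2,.005
1,8.3,24,3,.001
1,8.3,14,3,.024
1,1.7,9,2,.012
1,15.2,18,3,.008
1,15.2,21,1,.026
1,10.1,17,1,.048
1,2.1,20,1,.019
1,2.1,12,2,.036
1,8.6,2,2,.047
1,9.3,6,3,.017
1,13.5,21,1,.016
1,13.5,18,2,.028
1,5.5,13,2,.002
1,8.4,14,4,.006
1,8.4,24,2,.023
1,8.4,10,2,.036
1,7.8,7,1,.038
1,10.7,18,1,.036
1,13.3,17,1,.048
2,5.1,17,19,<.001
2,5.3,17,16,<.001
2,9.2,17,9,<.001
2,5.6,17,5,.006
2,13.2,17,7,.014
2,5.2,17,4,.025
2,10.1,17,1,.048
2,13.3,17,1,.048
2,8.3,24,3,.001
2,7.1,24,6,.002
2,12.1,24,3,.020
2,8.4,24,2,.023
2,2.3,14,18,<.001
2,1.4,14,14,.001
2,1.1,14,15,.003
2,8.4,14,4,.006
2,8.2,14,5,.016
2,1.6,14,3,.019
2,2.4,14,5,.024
2,8.3,14,3,.024
2,8.7,4,28,<.001
2,15.1,4,27,<.001
2,15.3,4,23,<.001
2,6.1,4,60,.003
2,1.2,4,65,.008
2,8.1,4,47,.013
2,11.2,4,12,.039
2,5.1,6,26,<.001
2,5.3,6,20,<.001
2,9.2,6,12,<.001
2,5.6,6,6,.005
2,9.3,6,3,.017
2,12.1,11,9,<.001
2,12.5,11,8,<.001
2,12.2,11,3,.004
2,1.2,11,9,.026
2,3.2,11,3,.026
2,7.1,11,5,.036
2,5.5,13,2,.002
2,5.6,13,2,.024
2,9.2,22,3,.005
2,2.7,22,2,.027
2,9.1,25,2,.007
2,1.6,9,3,.001
2,1.8,9,4,.002
2,1.3,9,4,.003
2,1.7,9,2,.012
2,5.1,8,28,.004
2,6.3,8,12,.043
2,5.1,1,18,<.001
2,5.3,1,13,.002
2,4.1,1,17,.013
2,2.2,1,13,.013
2,7.1,10,8,<.001
2,8.4,10,2,.036
2,15.2,18,3,.008
2,9.2,18,5,.023
2,13.5,18,2,.028
2,10.7,18,1,.036
2,5.1,26,10,<.001
2,2.1,20,1,.019
2,12.3,20,1,.027
2,10.3,7,2,.005
2,10.4,7,3,.020
2,7.8,7,1,.038
2,13.2,19,2,<.050
2,13.1,19,2,.011
2,8.1,2,24,<.001
2,6.1,2,17,.020
2,4.1,2,20,.024
2,1.2,2,18,.038
2,8.6,2,2,.047
2,3.1,12,34,<.001
2,12.2,12,6,<.001
2,3.2,12,4,.023
2,2.1,12,2,.036
2,6.2,12,9,.043
2,2.2,16,19,<.001
2,6.2,16,31,<.001
2,6.3,16,13,<.001
2,2.7,16,5,.020
2,6.1,23,3,.044
2,9.1,3,4,.023
2,3.1,3,5,.037
2,13.5,21,1,.016
2,15.2,21,1,.026
2,1.9,21,1,.039
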