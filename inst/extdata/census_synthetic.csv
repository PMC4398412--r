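# synthetic census fixtures generated by creolegame::synthesize_census()
# (not historical data); margin 0.06 from the desk-scale stripe
"territory","n_white","n_free_colored","n_slave","subdivision","year","creole_observed"
"synthetic_creole_01",22847,34081,131864,NA,NA,TRUE
"synthetic_creole_02",372,152,1529,NA,NA,TRUE
"synthetic_creole_03",300,495,5380,NA,NA,TRUE
"synthetic_creole_04",1226,218,5706,NA,NA,TRUE
"synthetic_creole_05",6057,348743,541703,NA,NA,TRUE
"synthetic_creole_06",508,259,1859,NA,NA,TRUE
"synthetic_creole_07",98,523,1080,NA,NA,TRUE
"synthetic_creole_08",575,440,4110,NA,NA,TRUE
"synthetic_creole_09",21455,34396,153409,NA,NA,TRUE
"synthetic_creole_10",149,932,3185,NA,NA,TRUE
"synthetic_noncreole_01",62547,3716,8614,NA,NA,FALSE
"synthetic_noncreole_02",235681,5451,18824,NA,NA,FALSE
"synthetic_noncreole_03",462710,42732,94341,NA,NA,FALSE
"synthetic_noncreole_04",171152,3897,70204,NA,NA,FALSE
"synthetic_noncreole_05",59,27,74,NA,NA,FALSE
"synthetic_noncreole_06",2085,82,702,NA,NA,FALSE
"synthetic_noncreole_07",3093,73,2011,NA,NA,FALSE
"synthetic_noncreole_08",2907,1019,1932,NA,NA,FALSE
"synthetic_noncreole_09",11745,48,85,NA,NA,FALSE
"synthetic_noncreole_10",73722,474,8420,NA,NA,FALSE
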