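database,subset,category,group_I,group_II,common
NCBI,all,genes_with_hits,57,38,NA
NCBI,all,redundant,516,294,165
NCBI,all,unique,125,90,5
NCBI,arabidopsis,genes_with_hits,8,6,NA
NCBI,arabidopsis,redundant,48,26,8
NCBI,arabidopsis,unique,20,4,0
NCBI,rice,genes_with_hits,10,13,NA
NCBI,rice,redundant,137,106,24
NCBI,rice,unique,77,20,4
NCBI,maize,genes_with_hits,10,9,NA
NCBI,maize,redundant,265,130,107
NCBI,maize,unique,12,50,0
PlantGDB,all,genes_with_hits,57,38,NA
PlantGDB,all,redundant,551,245,158
PlantGDB,all,unique,106,148,3
PlantGDB,arabidopsis,genes_with_hits,8,6,NA
PlantGDB,arabidopsis,redundant,35,22,5
PlantGDB,arabidopsis,unique,23,2,0
PlantGDB,rice,genes_with_hits,10,13,NA
PlantGDB,rice,redundant,106,53,9
PlantGDB,rice,unique,41,8,0
PlantGDB,maize,genes_with_hits,10,9,NA
PlantGDB,maize,redundant,355,148,128
PlantGDB,maize,unique,22,124,2
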