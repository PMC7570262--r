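"packet_id","species","cohort","site","plot","microhabitat","burial_seasons","collection_year","seeds_sown","n_expended","n_retained","n_assayed","n_stained"
"ex_001","E. mohavense","2015","site_1","plot_01","control",1,"2017",18,12,6,3,2
"ex_002","E. mohavense","2015","site_1","plot_01","runoff",1,"2017",18,13,5,3,1
"ex_003","E. mohavense","2015","site_1","plot_02","shade",1,"2017",18,11,7,4,2
"ex_004","E. mohavense","2015","site_1","plot_02","control",2,"2018",18,16,2,1,1
"ex_005","E. mohavense","2015","site_1","plot_03","shade",2,"2018",18,14,4,2,1
"ex_006","E. wallacei","2015","site_2","plot_01","control",1,"2017",14,3,11,6,2
"ex_007","E. wallacei","2015","site_2","plot_02","runoff",1,"2017",14,2,12,6,2
"ex_008","E. wallacei","2015","site_2","plot_02","shade",1,"2017",14,2,12,6,1
"ex_009","E. wallacei","2015","site_2","plot_03","shade",2,"2018",14,10,4,2,1
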