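individual_id,site_id,species,phenophase,date,status
I1,S1,acer_rubrum,breaking_leaf_buds,2015-03-31,no
I1,S1,acer_rubrum,breaking_leaf_buds,2015-04-10,yes
I1,S1,acer_rubrum,breaking_leaf_buds,2015-04-17,yes
I2,S1,acer_rubrum,breaking_leaf_buds,2015-03-01,no
I2,S1,acer_rubrum,breaking_leaf_buds,2015-04-10,yes
I3,S1,acer_rubrum,breaking_leaf_buds,2015-04-01,no
I3,S1,acer_rubrum,breaking_leaf_buds,2015-04-02,yes
I4,S1,acer_rubrum,breaking_leaf_buds,2015-03-21,no
I4,S1,acer_rubrum,breaking_leaf_buds,2015-04-10,yes
I5,S2,acer_rubrum,breaking_leaf_buds,2015-06-20,no
I5,S2,acer_rubrum,breaking_leaf_buds,2015-06-30,yes
I6,S2,acer_rubrum,open_flowers,2015-07-20,no
I6,S2,acer_rubrum,open_flowers,2015-07-30,yes
I7,S1,acer_rubrum,breaking_leaf_buds,2015-04-01,no
I7,S1,acer_rubrum,breaking_leaf_buds,2015-04-05,unsure
I7,S1,acer_rubrum,breaking_leaf_buds,2015-04-10,yes
I8,S1,acer_rubrum,breaking_leaf_buds,2015-04-15,yes
I9,S1,acer_rubrum,breaking_leaf_buds,2015-04-04,no
I9,S1,acer_rubrum,breaking_leaf_buds,2015-04-08,no
I9,S1,acer_rubrum,breaking_leaf_buds,2015-04-08,yes
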