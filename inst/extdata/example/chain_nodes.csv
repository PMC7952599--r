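id,name,node_type,biomass,abundance,life_stage,group,vulnerable
cordgrass,Pacific cordgrass,species,5200,18000,adult,plant,FALSE
snail,horn snail,species,310,9500,adult,invertebrate,FALSE
killifish,California killifish,species,42,1200,adult,fish,TRUE
egret,great egret,species,6,15,adult,bird,FALSE
birdwatching,birdwatching,service,,,,,
shoreline_stabilization,shoreline stabilization,service,,,,,
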