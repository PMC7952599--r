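source,target,link_type
cordgrass,snail,trophic
snail,killifish,trophic
killifish,egret,trophic
egret,birdwatching,provision
cordgrass,shoreline_stabilization,provision
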