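Place the filtered empirical salt-marsh web tables here to activate the
exact structural-count checks in the test suite:

  csm_nodes.csv / csm_links.csv   Carpinteria Salt Marsh   (107 species, 1015 trophic links)
  bsq_nodes.csv / bsq_links.csv   Bahia Falsa San Quintin  (122 species, 1060 trophic links)
  epb_nodes.csv / epb_links.csv   Estero de Punta Banda    (136 species, 1680 trophic links)

Files use the package CSV exchange format (see ?read_network):
  nodes: id,name,node_type,biomass,abundance,life_stage,group,vulnerable
  links: source,target,link_type{trophic|provision}

The data are distributed as supplementary files of the source study and
are not redistributed with this package.
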