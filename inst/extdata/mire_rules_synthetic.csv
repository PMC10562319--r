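# SYNTHETIC mire classification rule table (full coverage of the attribute
# domain). Classes: 1 productive forested mires, 2 sedge fens, 3 other open
# and sparsely treed fens, 4 ombrotrophic bogs.
productivity,main_class,fertility,mire_class
productive,spruce_mire,herb_rich,1
poorly_productive,spruce_mire,herb_rich,3
unproductive,spruce_mire,herb_rich,3
productive,pine_mire,herb_rich,1
poorly_productive,pine_mire,herb_rich,3
unproductive,pine_mire,herb_rich,3
productive,open_bog,herb_rich,2
poorly_productive,open_bog,herb_rich,2
unproductive,open_bog,herb_rich,2
productive,spruce_mire,mesotrophic,1
poorly_productive,spruce_mire,mesotrophic,3
unproductive,spruce_mire,mesotrophic,3
productive,pine_mire,mesotrophic,1
poorly_productive,pine_mire,mesotrophic,3
unproductive,pine_mire,mesotrophic,3
productive,open_bog,mesotrophic,2
poorly_productive,open_bog,mesotrophic,2
unproductive,open_bog,mesotrophic,2
productive,spruce_mire,oligotrophic,1
poorly_productive,spruce_mire,oligotrophic,3
unproductive,spruce_mire,oligotrophic,3
productive,pine_mire,oligotrophic,1
poorly_productive,pine_mire,oligotrophic,3
unproductive,pine_mire,oligotrophic,3
productive,open_bog,oligotrophic,3
poorly_productive,open_bog,oligotrophic,3
unproductive,open_bog,oligotrophic,3
productive,spruce_mire,ombrotrophic,1
poorly_productive,spruce_mire,ombrotrophic,4
unproductive,spruce_mire,ombrotrophic,4
productive,pine_mire,ombrotrophic,1
poorly_productive,pine_mire,ombrotrophic,4
unproductive,pine_mire,ombrotrophic,4
productive,open_bog,ombrotrophic,4
poorly_productive,open_bog,ombrotrophic,4
unproductive,open_bog,ombrotrophic,4
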