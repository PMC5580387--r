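"specimen_id","taxon","age_class","locality","provenance","a","b","c","d","e","f","g","h","i","j","k","l","facet_left","facet_right","position_note","position_asymmetry"
"RGM 139671","Coelodonta antiquitatis","unknown","","T1","T","T","T","T","T","C","T","C","T","T","T","T","","","",""
"RGM 146833","Coelodonta antiquitatis","adult","North Sea, 52 30N, 2 30E","C/T","T","C","?","C","C","X","T","?","?","X","X","X","small","small","small anterior rib facets relative to a T1",""
"RGM 171525","Coelodonta antiquitatis","adult","The Netherlands, Schaar van Colijnsplaat, prov. Zeeland, 51 36N, 3 52E","C7","C","C","?","X","C","X","C","C","C","C","C","C","","","",""
"RGM 369367","Coelodonta antiquitatis","juvenile","North Sea, South of Bruine Bank","C7","C","C","C","C","C","X","C","C","C","C","C","C","","","",""
"RGM 369657","Coelodonta antiquitatis","adult","North Sea, Bruine Bank, between 52 50 and 53 00N, 2 50 and 3 00E","C7","C","C","?","X","C","C","C","C","C","C","C","C","","","",""
"RGM 445933","Coelodonta antiquitatis","adult","The Netherlands, Westerschelde, Ellewoutsdijk, prov. Zeeland","C/T","T","C","?","C","C","X","C","?","?","C","T","X","","","asymmetric in size and position of the rib facet","TRUE"
"RGM 55336","Coelodonta antiquitatis","unknown","","T1","T","T","T","T","T","X","T","?","?","T","T","T","","","",""
"RGM 93477","Coelodonta antiquitatis","adult","The Netherlands, Westerschelde, Ellewoutsdijk, prov. Zeeland","C/T","X","T","C","T","X","X","C","?","?","X","T","T","small","small","small anterior rib facets relative to a T1",""
"RGM 93479","Coelodonta antiquitatis","unknown","","T1","T","T","T","T","T","C","T","T","T","T","T","T","","","",""
"RGM 93485","Coelodonta antiquitatis","unknown","","T1","T","?","?","T","C","T","T","?","?","T","T","T","","","",""
"RGM 93790","Coelodonta antiquitatis","adult","The Netherlands, between Zuid Willemsvaart en AA, 's Hertogenbosch, prov. N. Brabant","C/T","X","T","X","X","C","X","T","?","?","X","X","X","","","conspicuous asymmetry in rib facet size and other shape parameters","TRUE"
"RGM 94549","Coelodonta antiquitatis","juvenile","The Netherlands, Westerschelde, Ellewoutsdijk, prov. Zeeland","C/T","T","X","C","X","C","C","C","C","C","X","T","X","small","large","left anterior rib facet smaller and more dorsal; transverse and mammillary processes asymmetrically placed","TRUE"
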