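"specimen_id","taxon","age_class","locality","provenance","a","b","c","d","e","f","g","h","i","j","k","l","facet_left","facet_right","position_note","position_asymmetry"
"RGM 123268","Coelodonta antiquitatis","adult","North Sea, Bruine Bank, 52 45N, 2 40E","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 123886","Coelodonta antiquitatis","adult","North Sea, 30-40 miles WNW of IJmuiden","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 124895","Coelodonta antiquitatis","adult","North Sea, 52 27N, 2 25E","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 132637","Coelodonta antiquitatis","adult","North Sea, Bruine Bank, 52 40N, 2 55E","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 133133","Coelodonta antiquitatis","adult","North Sea, South of Bruine Bank","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 138907","Coelodonta antiquitatis","unknown","North Sea, Bruine Bank, 52 30N, 3 00E","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 139898","Coelodonta antiquitatis","adult","The Netherlands, Zuid-Willemsvaart, 's-Hertogenbosch, prov. N. Brabant","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 146833","Coelodonta antiquitatis","adult","North Sea, 52 30N, 2 30E","C/T","T","C","?","C","C","X","T","?","?","X","X","X","small","small","small anterior rib facets relative to a T1",""
"RGM 152631","Coelodonta antiquitatis","adult","North Sea, Bruine Bank, 52 30N, 3 00E","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 152709","Coelodonta antiquitatis","adult","North Sea, Bruine Bank, 52 37N, 3 02E","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 153522","Coelodonta antiquitatis","adult","North Sea, Bruine Bank, 52 10N, 2 50E","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 171473","Coelodonta antiquitatis","adult","The Netherlands, Schaar van Colijnsplaat, prov. Zeeland","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 171525","Coelodonta antiquitatis","adult","The Netherlands, Schaar van Colijnsplaat, prov. Zeeland, 51 36N, 3 52E","C7","C","C","?","X","C","X","C","C","C","C","C","C","","","",""
"RGM 171542","Coelodonta antiquitatis","adult","The Netherlands, Schaar van Colijnsplaat, prov. Zeeland","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 369367","Coelodonta antiquitatis","juvenile","North Sea, South of Bruine Bank","C7","C","C","C","C","C","X","C","C","C","C","C","C","","","",""
"RGM 369657","Coelodonta antiquitatis","adult","North Sea, Bruine Bank, between 52 50 and 53 00N, 2 50 and 3 00E","C7","C","C","?","X","C","C","C","C","C","C","C","C","","","",""
"RGM 388048","Coelodonta antiquitatis","adult","North Sea, Bruine Bank, between 52 50 and 53 00N, 2 50 and 3 00E","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 388049","Coelodonta antiquitatis","juvenile","North Sea, Bruine Bank, between 52 30 and 53 00N, 2 50 and 3 00E","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 400927","Coelodonta antiquitatis","juvenile","North Sea, Bruine Bank, between 52 30 and 53 00, 2 50 and 3 00E","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 445933","Coelodonta antiquitatis","adult","The Netherlands, Westerschelde, Ellewoutsdijk, prov. Zeeland","C/T","T","C","?","C","C","X","C","?","?","C","T","X","","","asymmetric in size and position of the rib facet","TRUE"
"RGM 445939","Coelodonta antiquitatis","adult","The Netherlands, Ellewoutsdijk, Westerschelde, prov. Zeeland","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 55335","Coelodonta antiquitatis","juvenile","The Netherlands, Westerschelde, Plaat van Baarland, prov. Zeeland","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 58226","Coelodonta antiquitatis","juvenile","The Netherlands, Westerschelde, prov. Zeeland","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 63324","Coelodonta antiquitatis","juvenile","The Netherlands, Hollands Diep, east of Moerdijkbrug; prov. N. Brabant","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 92687","Coelodonta antiquitatis","adult","The Netherlands, 's-Hertogenbosch, between Zuid-Willemsvaart and Aa, prov. N. Brabant","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 93342","Coelodonta antiquitatis","adult","The Netherlands, Ellewoutsdijk, Westerschelde, prov. Zeeland","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 93408","Coelodonta antiquitatis","juvenile","The Netherlands, Ellewoutsdijk, Westerschelde, prov. Zeeland","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 93449","Coelodonta antiquitatis","adult","The Netherlands, Ellewoutsdijk, Westerschelde, prov. Zeeland","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 93473","Coelodonta antiquitatis","juvenile","The Netherlands, Ellewoutsdijk, Westerschelde, prov. Zeeland","C7","C","C","C","C","C","C","C","C","C","C","C","C","","","",""
"RGM 93477","Coelodonta antiquitatis","adult","The Netherlands, Westerschelde, Ellewoutsdijk, prov. Zeeland","C/T","X","T","C","T","X","X","C","?","?","X","T","T","small","small","small anterior rib facets relative to a T1",""
"RGM 93790","Coelodonta antiquitatis","adult","The Netherlands, between Zuid Willemsvaart en AA, 's Hertogenbosch, prov. N. Brabant","C/T","X","T","X","X","C","X","T","?","?","X","X","X","","","conspicuous asymmetry in rib facet size and other shape parameters","TRUE"
"RGM 94549","Coelodonta antiquitatis","juvenile","The Netherlands, Westerschelde, Ellewoutsdijk, prov. Zeeland","C/T","T","X","C","X","C","C","C","C","C","X","T","X","small","large","left anterior rib facet smaller and more dorsal; transverse and mammillary processes asymmetrically placed","TRUE"
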