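"specimen_id","taxon","age_class","locality","provenance","a","b","c","d","e","f","g","h","i","j","k","l"
"RGM cat a (sumatrensis)","Dicerorhinus sumatrensis","adult","Indonesia, Sumatra, Padang besi","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"RGM cat b","Dicerorhinus sumatrensis","adult","Indonesia, Sumatra","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"RGM cat g","Dicerorhinus sumatrensis","adult","Indonesia, Sumatra","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"MNHN-ZM-AC-1887-932","Dicerorhinus sumatrensis","adult","Indonesia, Sumatra","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"ZMUC CN3791","Dicerorhinus sumatrensis","adult","Indonesia, Sumatra","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 54763","Dicerorhinus sumatrensis","juvenile","Burma; foramen transversarium at right side","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 54764","Dicerorhinus sumatrensis","juvenile","Burma","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 81892","Dicerorhinus sumatrensis","adult","Malaysia","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"NRM 592359","Ceratotherium simum","unknown","South Africa, Zululand","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"NMW 3086","Ceratotherium simum","adult","Sudan, Lado, Equatoria Prov.","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"MNHN-ZM-AC-A7968","Ceratotherium simum","adult","South Africa, Cape of Good Hope","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"ZMUC CN2662","Ceratotherium simum","adult","Sudan, Joknyang forest, near Jur river","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"FMNH 29174","Ceratotherium simum","adult","Uganda, White Nile District, Rhino Camp","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"FMNH 125413","Ceratotherium simum","adult","South Africa, Natal Province, Zululand District","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 51855","Ceratotherium simum","adult","Zaire","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 51856","Ceratotherium simum","adult","Zaire","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 51857","Ceratotherium simum","adult","Zaire","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 51858","Ceratotherium simum","adult","Zaire","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 51859","Ceratotherium simum","adult","Zaire","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 51860","Ceratotherium simum","adult","Zaire","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 51861","Ceratotherium simum","adult","Zaire","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 51862","Ceratotherium simum","juvenile","Zaire","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"MNHN-ZM-AC-1960-59","Rhinoceros unicornis","adult","","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"MNHN 1792","Rhinoceros unicornis","adult","","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"MNHN-ZM-AC-1967-101","Rhinoceros unicornis","adult","","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 35759","Rhinoceros unicornis","adult","","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 54454","Rhinoceros unicornis","adult","India","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 54456","Rhinoceros unicornis","adult","India","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 119475","Rhinoceros unicornis","juvenile","","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"FMNH 57639","Rhinoceros unicornis","adult","","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"RGM cat a (sondaicus)","Rhinoceros sondaicus","adult","Indonesia, Java","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"RGM cat c","Rhinoceros sondaicus","adult","Indonesia, Java","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"RGM ZMA 507","Rhinoceros sondaicus","unknown","Indonesia, Java","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"MNHN-ZM-AC-A7970","Rhinoceros sondaicus","adult","","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"MNHN-ZM-AC-A7971","Rhinoceros sondaicus","juvenile","Indonesia, Java","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"ZMUC CN 26","Rhinoceros sondaicus","adult","Indonesia, Java","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"RGM cat a (bicornis)","Diceros bicornis","adult","South Africa, Cape of Good Hope","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"RGM ZMA 506","Diceros bicornis","adult","","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"RGM 5738","Diceros bicornis","adult","","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"MNHN-ZM-AC-1941-208","Diceros bicornis","juvenile","","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"MNHN-ZM-AC-1944-278","Diceros bicornis","adult","","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"MNHN-ZM-AC-1936-644","Diceros bicornis","adult","","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"MNHN-ZM-AC-A7969","Diceros bicornis","adult","South Africa, Cape of Good Hope","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"ZMUC CN36..","Diceros bicornis","adult","Ethiopia, Abessnie","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"ZMUC CN 3653","Diceros bicornis","adult","Africa","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"ZMUC CN 4435","Diceros bicornis","adult","Kenya, Machanga","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 14136","Diceros bicornis","adult","","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 27757","Diceros bicornis","juvenile","Zaire","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 34739","Diceros bicornis","adult","Kenya","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 35319","Diceros bicornis","juvenile","","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 81805","Diceros bicornis","juvenile","South Africa","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 113776","Diceros bicornis","adult","Zaire","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 113777","Diceros bicornis","adult","","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"AMNH 245690","Diceros bicornis","adult","","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"FMNH 57809","Diceros bicornis","adult","Africa, Oideani Mountains","C7","C","C","C","C","C","C","C","C","C","C","C","C"
"FMNH 127848","Diceros bicornis","adult","Tanzania","C7","C","C","C","C","C","C","C","C","C","C","C","C"
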