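"id","anatomical_element","view","c7_criterion","t1_criterion","quantitative","bilateral","age_variant"
"a","centrum","rostral","Anterior articular face oval, higher than wide, dorsal border convex","Anterior articular face heart-shaped, at least as wide as high, dorsal border approx. straight",FALSE,FALSE,FALSE
"b","centrum","caudal","Adult: dorsal width clearly exceeds ventral width, may have dimple midway dorsally, ventrally convex. Juvenile: wider than high (height at least 69% of width), ventrally rounded, shallow dorsal dimple, indistinct trace of rib facets","Adult: squarish, dorsal width approx. equals ventral width, ventrally straight or tapering. Juvenile: wider than high (height less than 64% of width), ventrally tapering, sharp dorsal dimple, prominent impression of rib facets",TRUE,FALSE,TRUE
"c","centrum","ventral","Ventral keel with single or bilateral median tubercle, strongly developed","No ventral tubercles, keel at most very weakly developed",FALSE,FALSE,FALSE
"d","centrum","ventral","Anterior articular face deep and rounded, A-P length approx. 40-50% of centrum width","Anterior articular face shallow and flat, A-P length approx. 25-35% of centrum width",TRUE,FALSE,FALSE
"e","vertebral_foramen","rostral","Vertebral foramen wide (large), height/width ratio 75% or more","Vertebral foramen narrow (small), height/width ratio 73% or smaller",TRUE,FALSE,FALSE
"f","prezygapophysis","rostral","Prezygapophyses widely spaced, shortest distance approx. 50% of total width at same level","Prezygapophyses narrowly spaced, shortest distance approx. 35% of total width at same level",TRUE,TRUE,FALSE
"g","prezygapophysis","dorsal","Prezygapophysis more anterior than transverse process","Prezygapophysis overhangs transverse process",FALSE,FALSE,FALSE
"h","postzygapophysis","lateral","Postzygapophyseal facet visible for greatest part in lateral view (latero-caudally directed)","Postzygapophyseal facet at most minimally visible in lateral view (caudally directed)",FALSE,TRUE,FALSE
"i","postzygapophysis","caudal","Postzygapophyseal facets widely spaced (inner side lateral of neural spine)","Postzygapophyseal facets narrowly spaced (inner side close to centre of neural spine)",FALSE,TRUE,FALSE
"j","MPT_arch","rostral","MPT arch long, at least 85% of centrum height","MPT arch short, at most 70% of centrum height",TRUE,TRUE,FALSE
"k","rib_facet","lateral","Rib facet at transverse process absent","Rib facet at transverse process present (large)",FALSE,TRUE,FALSE
"l","rib_facet","rostral","Rib facet at centrum absent","Rib facet at centrum present (large)",FALSE,TRUE,FALSE
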