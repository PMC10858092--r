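athlete_id,kind,duration_s,quantity
gebrselassie,distance,213.73,1500.000
gebrselassie,distance,232.39,1609.344
gebrselassie,distance,292.86,2000.000
gebrselassie,distance,445.09,3000.000
gebrselassie,distance,481.08,3218.688
gebrselassie,distance,759.00,5000.000
gebrselassie,distance,1582.75,10000.000
gebrselassie,distance,1622.00,10000.000
gebrselassie,distance,3535.00,21097.500
gebrselassie,distance,7439.00,42195.000
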