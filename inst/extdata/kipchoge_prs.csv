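athlete_id,kind,duration_s,quantity
kipchoge,distance,213.20,1500.000
kipchoge,distance,230.40,1609.344
kipchoge,distance,447.66,3000.000
kipchoge,distance,766.53,5000.000
kipchoge,distance,791.00,5000.000
kipchoge,distance,1691.00,10000.000
kipchoge,distance,3565.00,21097.500
kipchoge,distance,7299.00,42195.000
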