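animal_id,instrument_date,total_d,at_sea_d,n_trips,mean_distance_km,sd_distance_km,mean_duration_d,sd_duration_d,mean_speed_kmh,sd_speed_kmh,mean_dive_depth_m,sd_dive_depth_m,max_dive_depth_m
West Is.,2009-12-11,160.5,106.3,19,350.9,44.5,5.6,0.8,2.6,0.4,86.3,19.4,137.5
Nicholas Baudin,2009-12-08,178.6,120.3,29,216.3,73.9,4.1,1.2,2.2,0.5,65.7,16.5,101.5
West Waldegrave,2009-12-10,205.7,110,42,113.5,52.1,2.6,1.3,1.9,0.7,55.7,15.7,88.5
Price Is.,2009-11-28,213.4,51.8,33,43.4,32.9,1.6,1,1.2,1.1,15.2,7.13,50.5
Liguanea,2009-11-29,99.1,52.8,25,82.1,62.1,2.1,1.6,1.7,0.8,83.9,32.1,129.5
Seal Bay,2009-12-03,175.1,123.8,23,299.8,33.9,5.4,0.6,2.3,0.3,79.2,18.6,105.3
Seal Slide,2009-11-07,179.9,96.8,27,69.7,26.31,3.6,0.8,1,0.3,49.7,14.5,68.5
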