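taxon,rank,paleo_lat,paleo_lon,age_max,age_min
Coralites primus,species,2.5,24.0,140,120
Coralites primus,species,-4.0,30.5,135,110
Coralites secundus,species,12.0,41.0,128,100
Coralites secundus,species,18.5,38.0,120,95
Astrodemo tethyensis,species,24.0,22.5,115,90
Astrodemo tethyensis,species,-28.0,35.0,110,85
Astrodemo tethyensis,species,31.0,28.0,100,80
Favosimilis notialis,species,-15.5,48.0,95,70
Favosimilis notialis,species,-22.0,55.5,92,66
Favosimilis borealis,species,27.5,18.0,90,60
Favosimilis borealis,species,33.5,26.0,85,55
Porimima occidentalis,species,8.0,-12.0,80,50
Porimima occidentalis,species,14.5,-6.5,76,48
Porimima occidentalis,species,-9.0,-2.0,72,45
Acroporoides gondwanae,species,-30.0,44.0,70,40
Acroporoides gondwanae,species,-35.5,52.0,66,38
Acroporoides gondwanae,species,-18.0,60.0,62,35
Stylomima australis,species,-26.5,112.0,60,30
Stylomima australis,species,-31.0,118.5,58,28
Stylomima australis,species,-24.0,125.0,55,25
Montimima iaaensis,species,-5.0,105.0,50,20
Montimima iaaensis,species,0.5,112.5,48,18
Montimima iaaensis,species,6.0,120.0,45,15
Montimima iaaensis,species,-2.5,128.0,40,12
Pocillodemo orientalis,species,10.0,135.0,38,10
Pocillodemo orientalis,species,15.5,128.5,35,8
Pocillodemo orientalis,species,21.0,122.0,30,5
Seriatomima relicta,species,-12.0,142.0,28,4
Seriatomima relicta,species,-8.5,150.5,25,2
Seriatomima relicta,species,-16.0,146.0,20,0
Galaxeopsis vagans,species,26.0,95.0,18,0
Galaxeopsis vagans,species,29.5,88.0,15,0
Galaxeopsis vagans,species,-33.0,102.0,12,0
Leptomima extrema,species,35.0,60.0,10,0
Leptomima extrema,species,-36.5,66.0,8,0
Leptomima extrema,species,32.0,72.0,5,0
Tubulodemo dubium,genus,40.0,30.0,60,20
Tubulodemo dubium,genus,-42.0,36.0,50,10
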