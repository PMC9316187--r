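element,ionization,wavelength_nm,fwhm_nm,signal_halfwidth_nm,bg_lo_start,bg_lo_end,bg_hi_start,bg_hi_end
C,I,247.856,0.10,0.30,246.256,247.056,248.656,249.456
Mn,II,257.610,0.10,0.30,256.010,256.810,258.410,259.210
Fe,II,259.940,0.10,0.30,258.410,259.210,260.740,261.540
Fe,II,274.640,0.10,0.30,273.040,273.840,275.440,276.240
Mg,II,279.550,0.10,0.30,277.800,278.600,281.200,282.000
Mg,II,280.270,0.10,0.30,277.800,278.600,281.200,282.000
Mg,I,285.213,0.10,0.30,283.613,284.413,286.013,286.813
Si,I,288.150,0.10,0.30,286.550,287.350,288.950,289.750
Al,I,309.270,0.10,0.30,307.670,308.470,310.070,310.870
Cu,I,324.750,0.10,0.30,323.150,323.950,325.550,326.350
CN,I,388.350,0.60,0.80,385.350,386.150,390.350,391.150
Ca,II,393.360,0.20,0.30,391.600,392.400,395.300,396.100
Al,I,394.400,0.20,0.30,391.600,392.400,395.300,396.100
Ca,I,422.670,0.20,0.30,421.070,421.870,423.470,424.270
Ca,I,442.540,0.20,0.30,440.800,441.600,444.500,445.300
Ca,I,443.590,0.20,0.30,440.800,441.600,444.500,445.300
Na,I,588.995,0.20,0.30,586.800,587.600,590.400,591.200
Na,I,589.590,0.20,0.30,586.800,587.600,590.400,591.200
Ca,I,610.270,0.20,0.30,608.400,609.200,613.200,614.000
Ca,I,612.220,0.20,0.30,608.400,609.200,613.200,614.000
Ca,I,643.900,0.20,0.30,642.300,643.100,644.700,645.500
K,I,766.490,0.20,0.30,764.300,765.100,768.200,769.000
K,I,769.900,0.20,0.30,768.200,769.000,770.700,771.500
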