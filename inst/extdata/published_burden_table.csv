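"decade","ssp","rcp","central"
"2011-2020","SSP1","rcp45",0.77
"2011-2020","SSP1","rcp85",0.79
"2011-2020","SSP2","rcp45",0.8
"2011-2020","SSP2","rcp85",0.82
"2011-2020","SSP3","rcp45",0.81
"2011-2020","SSP3","rcp85",0.83
"2011-2020","SSP4","rcp45",0.8
"2011-2020","SSP4","rcp85",0.83
"2011-2020","SSP5","rcp45",0.77
"2011-2020","SSP5","rcp85",0.79
"2021-2030","SSP1","rcp45",0.67
"2021-2030","SSP1","rcp85",0.69
"2021-2030","SSP2","rcp45",0.73
"2021-2030","SSP2","rcp85",0.75
"2021-2030","SSP3","rcp45",0.8
"2021-2030","SSP3","rcp85",0.82
"2021-2030","SSP4","rcp45",0.76
"2021-2030","SSP4","rcp85",0.78
"2021-2030","SSP5","rcp45",0.65
"2021-2030","SSP5","rcp85",0.67
"2031-2040","SSP1","rcp45",0.62
"2031-2040","SSP1","rcp85",0.64
"2031-2040","SSP2","rcp45",0.7
"2031-2040","SSP2","rcp85",0.72
"2031-2040","SSP3","rcp45",0.83
"2031-2040","SSP3","rcp85",0.85
"2031-2040","SSP4","rcp45",0.75
"2031-2040","SSP4","rcp85",0.78
"2031-2040","SSP5","rcp45",0.57
"2031-2040","SSP5","rcp85",0.59
"2041-2050","SSP1","rcp45",0.56
"2041-2050","SSP1","rcp85",0.59
"2041-2050","SSP2","rcp45",0.66
"2041-2050","SSP2","rcp85",0.7
"2041-2050","SSP3","rcp45",0.84
"2041-2050","SSP3","rcp85",0.89
"2041-2050","SSP4","rcp45",0.73
"2041-2050","SSP4","rcp85",0.77
"2041-2050","SSP5","rcp45",0.5
"2041-2050","SSP5","rcp85",0.53
"2051-2060","SSP1","rcp45",0.47
"2051-2060","SSP1","rcp85",0.52
"2051-2060","SSP2","rcp45",0.59
"2051-2060","SSP2","rcp85",0.65
"2051-2060","SSP3","rcp45",0.84
"2051-2060","SSP3","rcp85",0.93
"2051-2060","SSP4","rcp45",0.66
"2051-2060","SSP4","rcp85",0.73
"2051-2060","SSP5","rcp45",0.41
"2051-2060","SSP5","rcp85",0.45
"2061-2070","SSP1","rcp45",0.39
"2061-2070","SSP1","rcp85",0.46
"2061-2070","SSP2","rcp45",0.5
"2061-2070","SSP2","rcp85",0.58
"2061-2070","SSP3","rcp45",0.8
"2061-2070","SSP3","rcp85",0.94
"2061-2070","SSP4","rcp45",0.55
"2061-2070","SSP4","rcp85",0.66
"2061-2070","SSP5","rcp45",0.32
"2061-2070","SSP5","rcp85",0.37
"2071-2080","SSP1","rcp45",0.3
"2071-2080","SSP1","rcp85",0.39
"2071-2080","SSP2","rcp45",0.4
"2071-2080","SSP2","rcp85",0.52
"2071-2080","SSP3","rcp45",0.73
"2071-2080","SSP3","rcp85",0.94
"2071-2080","SSP4","rcp45",0.44
"2071-2080","SSP4","rcp85",0.56
"2071-2080","SSP5","rcp45",0.24
"2071-2080","SSP5","rcp85",0.3
"2081-2090","SSP1","rcp45",0.23
"2081-2090","SSP1","rcp85",0.31
"2081-2090","SSP2","rcp45",0.33
"2081-2090","SSP2","rcp85",0.45
"2081-2090","SSP3","rcp45",0.68
"2081-2090","SSP3","rcp85",0.92
"2081-2090","SSP4","rcp45",0.34
"2081-2090","SSP4","rcp85",0.46
"2081-2090","SSP5","rcp45",0.17
"2081-2090","SSP5","rcp85",0.24
"2091-2100","SSP1","rcp45",0.18
"2091-2100","SSP1","rcp85",0.25
"2091-2100","SSP2","rcp45",0.28
"2091-2100","SSP2","rcp85",0.37
"2091-2100","SSP3","rcp45",0.66
"2091-2100","SSP3","rcp85",0.88
"2091-2100","SSP4","rcp45",0.28
"2091-2100","SSP4","rcp85",0.37
"2091-2100","SSP5","rcp45",0.14
"2091-2100","SSP5","rcp85",0.18
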