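trial,outcome,method,estimate,ci_low,ci_high,hedges_g
COBALT,continuous,ITT,-5.68,-7.95,-3.41,-0.42
GENPOD,continuous,ITT,-1.19,-2.90,0.52,-0.11
HEALTHLINES,continuous,ITT,-0.51,-1.52,0.49,-0.08
IPCRESS,continuous,ITT,-7.04,-10.05,-4.03,-0.57
MIR,continuous,ITT,-1.86,-3.95,0.23,-0.15
PANDA,continuous,ITT,-0.51,-1.33,0.31,-0.09
TREAD,continuous,ITT,-0.54,-3.06,1.98,-0.04
COBALT,continuous,PP,-7.47,-9.91,-5.03,-0.56
GENPOD,continuous,PP,-1.08,-3.00,0.85,-0.10
HEALTHLINES,continuous,PP,-0.87,-1.95,0.21,-0.14
IPCRESS,continuous,PP,-7.47,-10.87,-4.08,-0.60
MIR,continuous,PP,-2.25,-4.67,0.16,-0.18
PANDA,continuous,PP,-0.63,-1.47,0.21,-0.11
TREAD,continuous,PP,0.07,-2.90,3.04,0.01
COBALT,continuous,CACE,-8.53,-12.13,-4.93,-0.64
GENPOD,continuous,CACE,-1.08,-3.22,1.06,-0.10
HEALTHLINES,continuous,CACE,-0.61,-1.98,0.77,-0.10
IPCRESS,continuous,CACE,-11.41,-16.43,-6.39,-0.92
MIR,continuous,CACE,-2.55,-5.41,0.32,-0.20
PANDA,continuous,CACE,-0.66,-1.53,0.21,-0.11
TREAD,continuous,CACE,-1.16,-5.58,3.25,-0.09
COBALT,binary,ITT,3.30,2.12,5.13,NA
GENPOD,binary,ITT,1.06,0.70,1.61,NA
HEALTHLINES,binary,ITT,1.23,0.85,1.78,NA
IPCRESS,binary,ITT,2.43,1.24,4.78,NA
MIR,binary,ITT,1.43,0.96,2.12,NA
PANDA,binary,ITT,1.24,0.84,1.82,NA
TREAD,binary,ITT,0.67,0.40,1.12,NA
COBALT,binary,PP,3.76,2.32,6.08,NA
GENPOD,binary,PP,1.11,0.70,1.77,NA
HEALTHLINES,binary,PP,1.40,0.95,2.08,NA
IPCRESS,binary,PP,2.85,1.37,5.96,NA
MIR,binary,PP,1.55,0.99,2.42,NA
PANDA,binary,PP,1.28,0.85,1.92,NA
TREAD,binary,PP,0.68,0.37,1.24,NA
COBALT,binary,CACE,6.64,4.01,11.02,NA
GENPOD,binary,CACE,1.17,0.77,1.79,NA
HEALTHLINES,binary,CACE,1.29,0.89,1.90,NA
IPCRESS,binary,CACE,2.75,1.42,5.31,NA
MIR,binary,CACE,1.69,0.98,2.94,NA
PANDA,binary,CACE,1.28,0.84,1.93,NA
TREAD,binary,CACE,0.71,0.39,1.27,NA
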