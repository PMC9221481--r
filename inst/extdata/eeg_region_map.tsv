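sub_region	region	channels
FM	EEGcen	Fpz,Fz
C	EEGcen	FC1,FCz,FC2,C1,Cz,C2
CP	EEGcen	CP1,CP2
POc	EEGcen	Pz,POz,Oz
AFle	EEGle	Fp1,AF3,AF7,F1,F3,F5,F7
TLle	EEGle	FC3,FC5,FT7,C3,C5,T7,CP3,CP5,TP7,M1
POle	EEGle	P1,P3,P5,P7,PO3,PO5,PO7,O1
AFri	EEGri	Fp2,AF4,AF8,F2,F4,F6,F8
TLri	EEGri	FC4,FC6,FT8,C4,C6,T8,CP4,CP6,TP8,M2
POri	EEGri	P2,P4,P6,P8,PO4,PO6,PO8,O2
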