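Dana-Farber Cancer Institute
Memorial Sloan Kettering Cancer Center
MD Anderson Cancer Center
Mayo Clinic Comprehensive Cancer Center
Massachusetts General Hospital Cancer Center
Johns Hopkins Sidney Kimmel Comprehensive Cancer Center
Cleveland Clinic Taussig Cancer Center
Fred Hutchinson Cancer Center
Moffitt Cancer Center
City of Hope Comprehensive Cancer Center
Roswell Park Comprehensive Cancer Center
Fox Chase Cancer Center
Winship Cancer Institute of Emory University
Siteman Cancer Center
Huntsman Cancer Institute
UCSF Helen Diller Family Comprehensive Cancer Center
Smilow Cancer Hospital at Yale New Haven
University of Colorado Cancer Center
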