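reader_id,study_id,frr,arterial,capillary,venous,overall
R1,S01,50,4,4,3,2
R2,S01,50,2,2,3,3
R3,S01,50,5,4,3,4
R1,S02,50,2,3,5,5
R2,S02,50,3,3,2,2
R3,S02,50,4,2,2,5
R1,S03,50,1,1,4,4
R2,S03,50,2,3,2,2
R3,S03,50,3,2,4,3
R1,S04,50,3,4,1,3
R2,S04,50,3,3,4,1
R3,S04,50,3,3,3,3
R1,S05,50,2,3,2,3
R2,S05,50,4,2,3,2
R3,S05,50,2,3,3,5
R1,S06,50,3,3,4,3
R2,S06,50,4,4,4,3
R3,S06,50,3,4,3,3
R1,S07,50,3,5,4,3
R2,S07,50,3,1,3,5
R3,S07,50,3,3,4,1
R1,S08,50,3,3,1,2
R2,S08,50,4,3,2,2
R3,S08,50,3,3,3,3
R1,S01,66,3,4,4,3
R2,S01,66,2,4,3,2
R3,S01,66,3,2,3,3
R1,S02,66,2,3,3,2
R2,S02,66,1,3,4,2
R3,S02,66,3,3,2,2
R1,S03,66,3,4,2,3
R2,S03,66,5,4,2,5
R3,S03,66,5,4,2,3
R1,S04,66,4,3,3,4
R2,S04,66,2,3,4,4
R3,S04,66,2,3,3,2
R1,S05,66,2,3,3,3
R2,S05,66,4,2,3,4
R3,S05,66,3,4,3,3
R1,S06,66,4,4,5,2
R2,S06,66,2,2,4,3
R3,S06,66,2,2,4,4
R1,S07,66,4,2,4,4
R2,S07,66,3,2,3,3
R3,S07,66,2,2,3,4
R1,S08,66,3,5,2,3
R2,S08,66,4,3,4,3
R3,S08,66,4,3,2,3
R1,S01,75,4,4,2,3
R2,S01,75,3,3,2,3
R3,S01,75,4,4,3,3
R1,S02,75,3,4,1,4
R2,S02,75,3,4,3,4
R3,S02,75,4,3,4,3
R1,S03,75,4,4,2,3
R2,S03,75,3,1,4,3
R3,S03,75,4,2,3,3
R1,S04,75,3,2,2,5
R2,S04,75,2,2,4,2
R3,S04,75,4,4,2,3
R1,S05,75,3,2,5,4
R2,S05,75,3,4,2,3
R3,S05,75,3,2,4,4
R1,S06,75,2,2,1,5
R2,S06,75,4,2,3,5
R3,S06,75,2,3,2,1
R1,S07,75,4,2,4,2
R2,S07,75,2,4,2,3
R3,S07,75,4,3,3,3
R1,S08,75,2,3,1,4
R2,S08,75,4,3,2,3
R3,S08,75,3,4,4,4
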