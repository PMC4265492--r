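segment_id,tissue_ml,air_ml
LB1,37.156,412.844
LB2,40.44,439.56
LB3,59.007,460.993
LB4,30.702,219.298
LB5,29.127,200.873
RB1,39.595,460.405
RB2,42.498,477.502
RB3,51.833,508.167
LLL,206.897,1293.103
RLL,189.13,1260.87
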