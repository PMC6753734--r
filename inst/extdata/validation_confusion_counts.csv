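case,margin_cm,tp,tn,fp,fn
calibration,0,45,709,0,17
calibration,3,62,709,0,0
calibration,5,62,697,12,0
right_post,0,7,648,0,4
right_post,3,11,638,10,0
right_post,5,11,629,19,0
right_ant,0,3,670,0,8
right_ant,3,11,661,9,0
right_ant,5,11,638,32,0
left_post,0,6,650,0,5
left_post,3,11,638,12,0
left_post,5,11,629,21,0
left_ant,0,4,683,0,7
left_ant,3,11,666,17,0
left_ant,5,11,643,40,0
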