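x_deg,y_deg,is_edge,is_blind_spot
-9,27,TRUE,FALSE
-3,27,TRUE,FALSE
3,27,TRUE,FALSE
9,27,TRUE,FALSE
-15,21,TRUE,FALSE
-9,21,TRUE,FALSE
-3,21,FALSE,FALSE
3,21,FALSE,FALSE
9,21,TRUE,FALSE
15,21,TRUE,FALSE
-21,15,TRUE,FALSE
-15,15,TRUE,FALSE
-9,15,FALSE,FALSE
-3,15,FALSE,FALSE
3,15,FALSE,FALSE
9,15,FALSE,FALSE
15,15,TRUE,FALSE
21,15,TRUE,FALSE
-27,9,TRUE,FALSE
-21,9,TRUE,FALSE
-15,9,FALSE,FALSE
-9,9,FALSE,FALSE
-3,9,FALSE,FALSE
3,9,FALSE,FALSE
9,9,FALSE,FALSE
15,9,FALSE,FALSE
21,9,TRUE,FALSE
27,9,TRUE,FALSE
-27,3,TRUE,FALSE
-21,3,FALSE,FALSE
-15,3,FALSE,FALSE
-9,3,FALSE,FALSE
-3,3,FALSE,FALSE
3,3,FALSE,FALSE
9,3,FALSE,FALSE
15,3,FALSE,TRUE
21,3,FALSE,FALSE
27,3,TRUE,FALSE
-27,-3,TRUE,FALSE
-21,-3,FALSE,FALSE
-15,-3,FALSE,FALSE
-9,-3,FALSE,FALSE
-3,-3,FALSE,FALSE
3,-3,FALSE,FALSE
9,-3,FALSE,FALSE
15,-3,FALSE,TRUE
21,-3,FALSE,FALSE
27,-3,TRUE,FALSE
-27,-9,TRUE,FALSE
-21,-9,TRUE,FALSE
-15,-9,FALSE,FALSE
-9,-9,FALSE,FALSE
-3,-9,FALSE,FALSE
3,-9,FALSE,FALSE
9,-9,FALSE,FALSE
15,-9,FALSE,FALSE
21,-9,TRUE,FALSE
27,-9,TRUE,FALSE
-21,-15,TRUE,FALSE
-15,-15,TRUE,FALSE
-9,-15,FALSE,FALSE
-3,-15,FALSE,FALSE
3,-15,FALSE,FALSE
9,-15,FALSE,FALSE
15,-15,TRUE,FALSE
21,-15,TRUE,FALSE
-15,-21,TRUE,FALSE
-9,-21,TRUE,FALSE
-3,-21,FALSE,FALSE
3,-21,FALSE,FALSE
9,-21,TRUE,FALSE
15,-21,TRUE,FALSE
-9,-27,TRUE,FALSE
-3,-27,TRUE,FALSE
3,-27,TRUE,FALSE
9,-27,TRUE,FALSE
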