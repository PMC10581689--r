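## The seven joint angles of the arm model, proximal to distal:
## shoulder flexion-extension, shoulder abduction-adduction, humeral rotation,
## elbow flexion-extension, forearm pronation-supination, wrist
## flexion-extension, wrist radial-ulnar deviation.
ANGLE_COLS <- c("s_fe", "s_aa", "h_r", "e_fe", "f_ps", "w_fe", "w_ru")
PROXIMAL_COLS <- c("s_fe", "s_aa")
DISTAL_COLS <- c("h_r", "e_fe", "f_ps", "w_fe", "w_ru")
LOCATION_COLS <- c("x", "y", "z", "incl", "azim")
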