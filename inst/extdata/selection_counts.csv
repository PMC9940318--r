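section,row,standard_x,standard_n,computer_x,computer_n,printed_p
aortic_preference,A,12,80,9,80,0.641
aortic_preference,B,10,80,13,80,0.653
aortic_preference,C,50,80,47,80,0.746
aortic_preference,D,8,80,11,80,0.626
anaortic_preference,E,57,80,41,80,0.015
anaortic_preference,F,2,80,17,80,0.001
anaortic_preference,G,0,80,0,80,1
anaortic_preference,H,11,80,8,80,0.626
anaortic_preference,I,0,80,2,80,0.497
anaortic_preference,J,10,80,10,80,1
anaortic_preference,K,0,80,2,80,0.497
anaortic_preference,L,0,80,0,80,1
unsatisfactory_selected,aortic,4,80,0,80,0.641
unsatisfactory_selected,anaortic,17,80,1,80,0.001
ideal_selected,aortic,52,80,49,80,0.743
ideal_selected,anaortic,5,80,23,80,0.001
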