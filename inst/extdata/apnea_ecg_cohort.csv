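recording_id,subject_id,original_half,independent_train_flag
a01,p1,train,TRUE
a14,p1,train,TRUE
a02,p2,train,FALSE
x14,p2,test,FALSE
a03,p3,train,TRUE
x19,p3,test,TRUE
a04,p4,train,TRUE
a12,p4,train,TRUE
a05,p5,train,FALSE
a10,p5,train,FALSE
a20,p5,train,FALSE
x07,p5,test,FALSE
a06,p6,train,TRUE
x15,p6,test,TRUE
a07,p7,train,TRUE
a16,p7,train,TRUE
x01,p7,test,TRUE
x30,p7,test,TRUE
a08,p8,train,FALSE
a13,p8,train,FALSE
x20,p8,test,FALSE
a09,p9,train,FALSE
a18,p9,train,FALSE
a11,p10,train,TRUE
a15,p11,train,TRUE
x27,p11,test,TRUE
x28,p11,test,TRUE
a17,p12,train,TRUE
x12,p12,test,TRUE
a19,p13,train,FALSE
x05,p13,test,FALSE
x08,p13,test,FALSE
x25,p13,test,FALSE
b01,p14,train,TRUE
x03,p14,test,TRUE
b02,p15,train,FALSE
b03,p15,train,FALSE
x16,p15,test,FALSE
x21,p15,test,FALSE
b04,p16,train,FALSE
c08,p16,train,FALSE
b05,p17,train,TRUE
x11,p17,test,TRUE
c01,p18,train,FALSE
x35,p18,test,FALSE
c02,p19,train,TRUE
c09,p19,train,TRUE
c03,p20,train,FALSE
x04,p20,test,FALSE
c04,p21,train,TRUE
x29,p21,test,TRUE
c05,p22,train,FALSE
x33,p22,test,FALSE
c06,p23,train,TRUE
c07,p24,train,TRUE
x34,p24,test,TRUE
c10,p25,train,TRUE
x18,p25,test,TRUE
x02,p26,test,FALSE
x06,p27,test,TRUE
x24,p27,test,TRUE
x09,p28,test,TRUE
x23,p28,test,TRUE
x10,p29,test,FALSE
x13,p30,test,FALSE
x26,p30,test,FALSE
x17,p31,test,FALSE
x22,p31,test,FALSE
x31,p32,test,FALSE
x32,p32,test,FALSE
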