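class,range
coil,A:1
coil,A:5-11
coil,A:29
coil,A:44-56
coil,A:78-121
coil,A:125-152
coil,A:162-177
coil,A:184-190
coil,A:199-200
coil,A:204-210
coil,A:231-259
coil,A:265-269
coil,A:273-276
helix,A:12-28
helix,A:30-43
helix,A:57-77
helix,A:122-124
helix,A:153-161
helix,A:178-183
helix,A:191-198
helix,A:201-203
helix,A:211-230
helix,A:260-264
turn,A:2-4
turn,A:269-272
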