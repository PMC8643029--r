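# Example profile of four semi-labeled trees (fully labeled form).
# Numeric taxa 1-6 are the fresh labels added to the raw trees.
(((a,c)3,b)2,d)1;
(b,c,(e)g)4;
(f,(h,e)5,k)g;
((h)i,(k)j,l)6;
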