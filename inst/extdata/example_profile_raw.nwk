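# Example profile of four semi-labeled trees (raw form: internal nodes
# without a taxon are left unlabeled; see fully_label()).
(((a,c),b),d);
(b,c,(e)g);
(f,(h,e),k)g;
((h)i,(k)j,l);
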