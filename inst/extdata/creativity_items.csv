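item_id,scale_id,text
via_009,creativity,"I am always coming up with new ways to do things"
via_010,creativity,"I pride myself on being original"
via_011,creativity,"My friends say that I have lots of new and different ideas"
via_012,creativity,"I am an original thinker"
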