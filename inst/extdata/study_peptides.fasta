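>aurein2.5 C-terminally amidated
GLFDIVKKVVGAFGSL
>temporinL C-terminally amidated
FVQWFSKFLGRIL
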