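Facebook
Twitter
Facebook advertisement
Twitter advertisement
Friend or family member
Online support group
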