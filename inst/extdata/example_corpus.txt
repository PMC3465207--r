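det finding aux vbn
det finding aux vbn
det finding aux vbn
det finding aux vbn
det finding aux vbn
det finding aux vbn
det disease aux vbn
det disease aux vbn
det disease aux vbn
det disease aux vbn
det disease aux vbn
noun num unit adv
noun num unit adv
noun num unit adv
noun num unit adv
det finding prep bodypart aux vbn
det finding prep bodypart aux vbn
det finding prep bodypart aux vbn
pron aux vbn prep bodypart
pron aux vbn prep bodypart
pron aux vbn prep bodypart
det disease prep bodypart aux vbn
det disease prep bodypart aux vbn
noun verb det finding
noun verb det finding
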