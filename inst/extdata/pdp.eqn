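# Process dissociation procedure (PDP) for the race IAT: 8 condition cells,
# responses correct/incorrect, parameters A_White, A_Black (automatic
# evaluations; values > .5 mean a positive evaluation of the target group)
# and C_White, C_Black, C_good, C_bad (stimulus-specific control).
#
# Tree, per trial: control over the relevant stimulus category succeeds with
# probability C and always produces the correct response.  When control
# fails, the automatic evaluation drives the response toward the
# evaluation-consistent key.  On face trials the face's own automatic
# parameter applies: A is the probability of pressing the "good"-assigned
# key, which is correct for White faces in compatible blocks and for Black
# faces in incompatible blocks.  On attribute-word trials the automatic
# evaluation of the target category that currently shares the response key
# applies: good words are driven toward "good" with probability A_White
# (compatible) or A_Black (incompatible); bad words mirror this, the
# "bad"-assigned response being correct with probability 1-A of the paired
# target.
#
# condition response factor-product
White_compatible correct C_White
White_compatible correct (1-C_White)*A_White
White_compatible incorrect (1-C_White)*(1-A_White)
Black_compatible correct C_Black
Black_compatible correct (1-C_Black)*(1-A_Black)
Black_compatible incorrect (1-C_Black)*A_Black
good_compatible correct C_good
good_compatible correct (1-C_good)*A_White
good_compatible incorrect (1-C_good)*(1-A_White)
bad_compatible correct C_bad
bad_compatible correct (1-C_bad)*(1-A_Black)
bad_compatible incorrect (1-C_bad)*A_Black
White_incompatible correct C_White
White_incompatible correct (1-C_White)*(1-A_White)
White_incompatible incorrect (1-C_White)*A_White
Black_incompatible correct C_Black
Black_incompatible correct (1-C_Black)*A_Black
Black_incompatible incorrect (1-C_Black)*(1-A_Black)
good_incompatible correct C_good
good_incompatible correct (1-C_good)*A_Black
good_incompatible incorrect (1-C_good)*(1-A_Black)
bad_incompatible correct C_bad
bad_incompatible correct (1-C_bad)*(1-A_White)
bad_incompatible incorrect (1-C_bad)*A_White
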