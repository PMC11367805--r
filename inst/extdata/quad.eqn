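# Quad model for the race IAT: 8 condition cells (stimulus category x block
# compatibility), responses correct/incorrect, parameters AC_wg, AC_bb, D, OB, G.
#
# Tree, per trial: the relevant association (AC_wg on White faces and good
# words, AC_bb on Black faces and bad words) is activated with probability AC.
# Detection discerns the correct response with probability D.  In compatible
# blocks (White/good share a key) the association-driven response is correct,
# so activation yields a correct response whether or not detection succeeds.
# In incompatible blocks the association-driven response is wrong; when it
# conflicts with a detected correct response, Overcoming Bias (OB) must
# succeed for the correct response to be given, and a failed detection lets
# the association drive an error.  With neither association nor detection
# active, the participant guesses the key currently assigned to "good" with
# probability G.  The good-assigned key is correct for White faces and good
# words in compatible blocks, and for Black faces and good words in
# incompatible blocks.
#
# condition response factor-product
White_compatible correct AC_wg*D
White_compatible correct AC_wg*(1-D)
White_compatible correct (1-AC_wg)*D
White_compatible correct (1-AC_wg)*(1-D)*G
White_compatible incorrect (1-AC_wg)*(1-D)*(1-G)
Black_compatible correct AC_bb*D
Black_compatible correct AC_bb*(1-D)
Black_compatible correct (1-AC_bb)*D
Black_compatible correct (1-AC_bb)*(1-D)*(1-G)
Black_compatible incorrect (1-AC_bb)*(1-D)*G
good_compatible correct AC_wg*D
good_compatible correct AC_wg*(1-D)
good_compatible correct (1-AC_wg)*D
good_compatible correct (1-AC_wg)*(1-D)*G
good_compatible incorrect (1-AC_wg)*(1-D)*(1-G)
bad_compatible correct AC_bb*D
bad_compatible correct AC_bb*(1-D)
bad_compatible correct (1-AC_bb)*D
bad_compatible correct (1-AC_bb)*(1-D)*(1-G)
bad_compatible incorrect (1-AC_bb)*(1-D)*G
White_incompatible correct AC_wg*D*OB
White_incompatible incorrect AC_wg*D*(1-OB)
White_incompatible incorrect AC_wg*(1-D)
White_incompatible correct (1-AC_wg)*D
White_incompatible correct (1-AC_wg)*(1-D)*(1-G)
White_incompatible incorrect (1-AC_wg)*(1-D)*G
Black_incompatible correct AC_bb*D*OB
Black_incompatible incorrect AC_bb*D*(1-OB)
Black_incompatible incorrect AC_bb*(1-D)
Black_incompatible correct (1-AC_bb)*D
Black_incompatible correct (1-AC_bb)*(1-D)*G
Black_incompatible incorrect (1-AC_bb)*(1-D)*(1-G)
good_incompatible correct AC_wg*D*OB
good_incompatible incorrect AC_wg*D*(1-OB)
good_incompatible incorrect AC_wg*(1-D)
good_incompatible correct (1-AC_wg)*D
good_incompatible correct (1-AC_wg)*(1-D)*G
good_incompatible incorrect (1-AC_wg)*(1-D)*(1-G)
bad_incompatible correct AC_bb*D*OB
bad_incompatible incorrect AC_bb*D*(1-OB)
bad_incompatible incorrect AC_bb*(1-D)
bad_incompatible correct (1-AC_bb)*D
bad_incompatible correct (1-AC_bb)*(1-D)*(1-G)
bad_incompatible incorrect (1-AC_bb)*(1-D)*G
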