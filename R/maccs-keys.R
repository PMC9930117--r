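# The public 166-key MACCS structural key definitions (SMARTS form of the
# MDL keys as standardised in the open-source cheminformatics community).
# Each entry is (key number, SMARTS, count threshold): the key is set when
# the molecule has strictly more than `threshold` unique matches.  Three
# keys have no SMARTS form and are handled specially: key 1 (isotope) is
# never set here, key 125 (more than one aromatic ring) and key 166 (more
# than one connected fragment) are computed from the molecular graph.
maccs_key_table <- function() {
  tab <- list(
    list(1L, "?", 0L),
    list(2L, "[#104]", 0L),
    list(3L, "[#32,#33,#34,#50,#51,#52,#82,#83,#84]", 0L),
    list(4L, "[Ac,Th,Pa,U,Np,Pu,Am,Cm,Bk,Cf,Es,Fm,Md,No,Lr]", 0L),
    list(5L, "[Sc,Ti,Y,Zr,Hf]", 0L),
    list(6L, "[La,Ce,Pr,Nd,Pm,Sm,Eu,Gd,Tb,Dy,Ho,Er,Tm,Yb,Lu]", 0L),
    list(7L, "[V,Cr,Mn,Nb,Mo,Tc,Ta,W,Re]", 0L),
    list(8L, "[!#6;!#1]1~*~*~*~1", 0L),
    list(9L, "[Fe,Co,Ni,Ru,Rh,Pd,Os,Ir,Pt]", 0L),
    list(10L, "[Be,Mg,Ca,Sr,Ba,Ra]", 0L),
    list(11L, "*1~*~*~*~1", 0L),
    list(12L, "[Cu,Zn,Ag,Cd,Au,Hg]", 0L),
    list(13L, "[#8]~[#7](~[#6])~[#6]", 0L),
    list(14L, "[#16]-[#16]", 0L),
    list(15L, "[#8]~[#6](~[#8])~[#8]", 0L),
    list(16L, "[!#6;!#1]1~*~*~1", 0L),
    list(17L, "[#6]#[#6]", 0L),
    list(18L, "[#5,#13,#31,#49,#81]", 0L),
    list(19L, "*1~*~*~*~*~*~*~1", 0L),
    list(20L, "[#14]", 0L),
    list(21L, "[#6]=[#6](~[!#6;!#1])~[!#6;!#1]", 0L),
    list(22L, "*1~*~*~1", 0L),
    list(23L, "[#7]~[#6](~[#8])~[#8]", 0L),
    list(24L, "[#7]-[#8]", 0L),
    list(25L, "[#7]~[#6](~[#7])~[#7]", 0L),
    list(26L, "[#6]=;@[#6](@*)@*", 0L),
    list(27L, "[I]", 0L),
    list(28L, "[!#6;!#1]~[CH2]~[!#6;!#1]", 0L),
    list(29L, "[#15]", 0L),
    list(30L, "[#6]~[!#6;!#1](~[#6])(~[#6])~*", 0L),
    list(31L, "[!#6;!#1]~[F,Cl,Br,I]", 0L),
    list(32L, "[#6]~[#16]~[#7]", 0L),
    list(33L, "[#7]~[#16]", 0L),
    list(34L, "[CH2]=*", 0L),
    list(35L, "[Li,Na,K,Rb,Cs,Fr]", 0L),
    list(36L, "[#16R]", 0L),
    list(37L, "[#7]~[#6](~[#8])~[#7]", 0L),
    list(38L, "[#7]~[#6](~[#6])~[#7]", 0L),
    list(39L, "[#8]~[#16](~[#8])~[#8]", 0L),
    list(40L, "[#16]-[#8]", 0L),
    list(41L, "[#6]#[#7]", 0L),
    list(42L, "F", 0L),
    list(43L, "[!#6;!#1;!H0]~*~[!#6;!#1;!H0]", 0L),
    list(44L, "[!#1;!#6;!#7;!#8;!#9;!#14;!#15;!#16;!#17;!#35;!#53]", 0L),
    list(45L, "[#6]=[#6]~[#7]", 0L),
    list(46L, "Br", 0L),
    list(47L, "[#16]~*~[#7]", 0L),
    list(48L, "[#8]~[!#6;!#1](~[#8])(~[#8])", 0L),
    list(49L, "[!+0]", 0L),
    list(50L, "[#6]=[#6](~[#6])~[#6]", 0L),
    list(51L, "[#6]~[#16]~[#8]", 0L),
    list(52L, "[#7]~[#7]", 0L),
    list(53L, "[!#6;!#1;!H0]~*~*~*~[!#6;!#1;!H0]", 0L),
    list(54L, "[!#6;!#1;!H0]~*~*~[!#6;!#1;!H0]", 0L),
    list(55L, "[#8]~[#16]~[#8]", 0L),
    list(56L, "[#8]~[#7](~[#8])~[#6]", 0L),
    list(57L, "[#8R]", 0L),
    list(58L, "[!#6;!#1]~[#16]~[!#6;!#1]", 0L),
    list(59L, "[#16]!:*:*", 0L),
    list(60L, "[#16]=[#8]", 0L),
    list(61L, "*~[#16](~*)~*", 0L),
    list(62L, "*@*!@*@*", 0L),
    list(63L, "[#7]=[#8]", 0L),
    list(64L, "*@*!@[#16]", 0L),
    list(65L, "c:n", 0L),
    list(66L, "[#6]~[#6](~[#6])(~[#6])~*", 0L),
    list(67L, "[!#6;!#1]~[#16]", 0L),
    list(68L, "[!#6;!#1;!H0]~[!#6;!#1;!H0]", 0L),
    list(69L, "[!#6;!#1]~[!#6;!#1;!H0]", 0L),
    list(70L, "[!#6;!#1]~[#7]~[!#6;!#1]", 0L),
    list(71L, "[#7]~[#8]", 0L),
    list(72L, "[#8]~*~*~[#8]", 0L),
    list(73L, "[#16]=*", 0L),
    list(74L, "[CH3]~*~[CH3]", 0L),
    list(75L, "*!@[#7]@*", 0L),
    list(76L, "[#6]=[#6](~*)~*", 0L),
    list(77L, "[#7]~*~[#7]", 0L),
    list(78L, "[#6]=[#7]", 0L),
    list(79L, "[#7]~*~*~[#7]", 0L),
    list(80L, "[#7]~*~*~*~[#7]", 0L),
    list(81L, "[#16]~*(~*)~*", 0L),
    list(82L, "*~[CH2]~[!#6;!#1;!H0]", 0L),
    list(83L, "[!#6;!#1]1~*~*~*~*~1", 0L),
    list(84L, "[NH2]", 0L),
    list(85L, "[#6]~[#7](~[#6])~[#6]", 0L),
    list(86L, "[C;H2,H3][!#6;!#1][C;H2,H3]", 0L),
    list(87L, "[F,Cl,Br,I]!@*@*", 0L),
    list(88L, "[#16]", 0L),
    list(89L, "[#8]~*~*~*~[#8]", 0L),
    list(90L, "[$([!#6;!#1;!H0]~*~*~[CH2]~*),$([!#6;!#1;!H0;R]1@[R]@[R]@[CH2;R]1),$([!#6;!#1;!H0]~[R]1@[R]@[CH2;R]1)]", 0L),
    list(91L, "[$([!#6;!#1;!H0]~*~*~*~[CH2]~*),$([!#6;!#1;!H0;R]1@[R]@[R]@[R]@[CH2;R]1),$([!#6;!#1;!H0]~[R]1@[R]@[R]@[CH2;R]1),$([!#6;!#1;!H0]~*~[R]1@[R]@[CH2;R]1)]", 0L),
    list(92L, "[#8]~[#6](~[#7])~[#6]", 0L),
    list(93L, "[!#6;!#1]~[CH3]", 0L),
    list(94L, "[!#6;!#1]~[#7]", 0L),
    list(95L, "[#7]~*~*~[#8]", 0L),
    list(96L, "*1~*~*~*~*~1", 0L),
    list(97L, "[#7]~*~*~*~[#8]", 0L),
    list(98L, "[!#6;!#1]1~*~*~*~*~*~1", 0L),
    list(99L, "[#6]=[#6]", 0L),
    list(100L, "*~[CH2]~[#7]", 0L),
    list(101L, "[$([R]@1@[R]@[R]@[R]@[R]@[R]@[R]@[R]1),$([R]@1@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]1),$([R]@1@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]1),$([R]@1@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]1),$([R]@1@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]1),$([R]@1@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]1),$([R]@1@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]1)]", 0L),
    list(102L, "[!#6;!#1]~[#8]", 0L),
    list(103L, "Cl", 0L),
    list(104L, "[!#6;!#1;!H0]~*~[CH2]~*", 0L),
    list(105L, "*@*(@*)@*", 0L),
    list(106L, "[!#6;!#1]~*(~[!#6;!#1])~[!#6;!#1]", 0L),
    list(107L, "[F,Cl,Br,I]~*(~*)~*", 0L),
    list(108L, "[CH3]~*~*~*~[CH2]~*", 0L),
    list(109L, "*~[CH2]~[#8]", 0L),
    list(110L, "[#7]~[#6]~[#8]", 0L),
    list(111L, "[#7]~*~[CH2]~*", 0L),
    list(112L, "*~*(~*)(~*)~*", 0L),
    list(113L, "[#8]!:*:*", 0L),
    list(114L, "[CH3]~[CH2]~*", 0L),
    list(115L, "[CH3]~*~[CH2]~*", 0L),
    list(116L, "[$([CH3]~*~*~[CH2]~*),$([CH3]~*1~*~[CH2]1)]", 0L),
    list(117L, "[#7]~*~[#8]", 0L),
    list(118L, "[$(*~[CH2]~[CH2]~*),$(*1~[CH2]~[CH2]1)]", 1L),
    list(119L, "[#7]=*", 0L),
    list(120L, "[!#6;R]", 1L),
    list(121L, "[#7;R]", 0L),
    list(122L, "*~[#7](~*)~*", 0L),
    list(123L, "[#8]~[#6]~[#8]", 0L),
    list(124L, "[!#6;!#1]~[!#6;!#1]", 0L),
    list(125L, "?", 0L),
    list(126L, "*!@[#8]!@*", 0L),
    list(127L, "*@*!@[#8]", 1L),
    list(128L, "[$(*~[CH2]~*~*~*~[CH2]~*),$([R]1@[CH2;R]@[R]@[R]@[R]@[CH2;R]1),$(*~[CH2]~[R]1@[R]@[R]@[CH2;R]1),$(*~[CH2]~*~[R]1@[R]@[CH2;R]1)]", 0L),
    list(129L, "[$(*~[CH2]~*~*~[CH2]~*),$([R]1@[CH2]@[R]@[R]@[CH2;R]1),$(*~[CH2]~[R]1@[R]@[CH2;R]1)]", 0L),
    list(130L, "[!#6;!#1]~[!#6;!#1]", 1L),
    list(131L, "[!#6;!#1;!H0]", 1L),
    list(132L, "[#8]~*~[CH2]~*", 0L),
    list(133L, "*@*!@[#7]", 0L),
    list(134L, "[F,Cl,Br,I]", 0L),
    list(135L, "[#7]!:*:*", 0L),
    list(136L, "[#8]=*", 1L),
    list(137L, "[!C;!c;R]", 0L),
    list(138L, "[!#6;!#1]~[CH2]~*", 1L),
    list(139L, "[O;!H0]", 0L),
    list(140L, "[#8]", 3L),
    list(141L, "[CH3]", 2L),
    list(142L, "[#7]", 1L),
    list(143L, "*@*!@[#8]", 0L),
    list(144L, "*!:*:*!:*", 0L),
    list(145L, "*1~*~*~*~*~*~1", 1L),
    list(146L, "[#8]", 2L),
    list(147L, "[$(*~[CH2]~[CH2]~*),$([R]1@[CH2;R]@[CH2;R]1)]", 0L),
    list(148L, "*~[!#6;!#1](~*)~*", 0L),
    list(149L, "[C;H3,H4]", 1L),
    list(150L, "*!@*@*!@*", 0L),
    list(151L, "[#7;!H0]", 0L),
    list(152L, "[#8]~[#6](~[#6])~[#6]", 0L),
    list(153L, "[!#6;!#1]~[CH2]~*", 0L),
    list(154L, "[#6]=[#8]", 0L),
    list(155L, "*!@[CH2]!@*", 0L),
    list(156L, "[#7]~*(~*)~*", 0L),
    list(157L, "[#6]-[#8]", 0L),
    list(158L, "[#6]-[#7]", 0L),
    list(159L, "[#8]", 1L),
    list(160L, "[C;H3,H4]", 0L),
    list(161L, "[#7]", 0L),
    list(162L, "a", 0L),
    list(163L, "*1~*~*~*~*~*~1", 0L),
    list(164L, "[#8]", 0L),
    list(165L, "[R]", 0L),
    list(166L, "?", 0L)
  )
  tibble(
    key = vapply(tab, function(e) e[[1]], integer(1)),
    smarts = vapply(tab, function(e) e[[2]], character(1)),
    threshold = vapply(tab, function(e) e[[3]], integer(1))
  )
}
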