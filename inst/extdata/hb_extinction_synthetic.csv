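"wavelength_nm","extinction_1_per_M_cm"
420,265870.91
421,247484.44
422,230360.62
423,214450.37
424,199704.61
425,186074.24
426,173510.19
427,161963.37
428,151384.69
429,141725.08
430,132935.46
431,124966.44
432,117767.54
433,111287.97
434,105476.94
435,100283.68
436,95657.4
437,91547.32
438,87902.65
439,84672.62
440,81806.43
441,79254.73
442,76973.8
443,74921.37
444,73055.14
445,71332.83
446,69712.15
447,68150.81
448,66606.53
449,65037.02
450,63399.99
451,61664.13
452,59842.07
453,57957.39
454,56033.7
455,54094.59
456,52163.64
457,50264.47
458,48420.67
459,46655.83
460,44993.54
461,43451.95
462,42027.36
463,40710.64
464,39492.62
465,38364.16
466,37316.12
467,36339.35
468,35424.7
469,34563.01
470,33745.15
471,32963.62
472,32217.48
473,31507.47
474,30834.3
475,30198.71
476,29601.41
477,29043.14
478,28524.61
479,28046.54
480,27609.67
481,27213.59
482,26853.41
483,26523.11
484,26216.66
485,25928.05
486,25651.26
487,25380.28
488,25109.07
489,24831.63
490,24541.93
491,24235.78
492,23916.3
493,23588.44
494,23257.14
495,22927.36
496,22604.02
497,22292.1
498,21996.52
499,21722.23
500,21474.19
501,21258.02
502,21082.13
503,20955.59
504,20887.48
505,20886.89
506,20962.9
507,21121.01
508,21352.4
509,21644.69
510,21985.48
511,22363.63
512,22773.01
513,23208.75
514,23665.96
515,24139.77
516,24625.3
517,25117.67
518,25612.02
519,26103.45
520,26587.09
521,27061.89
522,27542.09
523,28045.74
524,28590.91
525,29195.66
526,29878.04
527,30656.12
528,31547.96
529,32571.62
530,33745.15
531,35080.06
532,36561.56
533,38168.3
534,39878.94
535,41672.12
536,43526.5
537,45420.73
538,47333.46
539,49243.34
540,51129.02
541,52900.95
542,54196.76
543,54684.12
544,54423.74
545,53574.56
546,52295.56
547,50745.67
548,49083.86
549,47443.4
550,45854.78
551,44322.84
552,42852.38
553,41448.22
554,40115.17
555,38858.06
556,37688.79
557,36647.7
558,35782.22
559,35139.75
560,34767.73
561,34701.98
562,34931.84
563,35435.06
564,36189.38
565,37172.53
566,38362.27
567,39736.33
568,41272.45
569,42948.38
570,44727.03
571,46512.03
572,48192.21
573,49656.37
574,50793.31
575,51491.86
576,51640.83
577,51129.02
578,49881.52
579,47968.51
580,45496.44
581,42571.75
582,39300.89
583,35790.31
584,32143.04
585,28448.4
586,24792.27
587,21260.57
588,17939.19
589,14914.02
590,12270.97
591,10073.44
592,8294.92
593,6886.43
594,5798.98
595,4983.55
596,4391.18
597,3972.85
598,3679.59
599,3462.38
600,3272.26
601,3069.25
602,2849.6
603,2618.55
604,2381.39
605,2143.37
606,1909.77
607,1685.85
608,1476.88
609,1288.12
610,1124.84
611,990.87
612,884.28
613,801.71
614,739.8
615,695.17
616,664.46
617,644.31
618,631.35
619,622.22
620,613.55
621,602.62
622,589.31
623,574.15
624,557.66
625,540.36
626,522.79
627,505.45
628,488.89
629,473.62
630,460.16
631,448.92
632,439.75
633,432.39
634,426.57
635,422.02
636,418.48
637,415.68
638,413.35
639,411.22
640,409.03
641,406.56
642,403.82
643,400.85
644,397.72
645,394.46
646,391.15
647,387.83
648,384.55
649,381.38
650,378.35
651,375.53
652,372.9
653,370.46
654,368.21
655,366.12
656,364.19
657,362.41
658,360.78
659,359.28
660,357.9
661,356.64
662,355.47
663,354.39
664,353.37
665,352.4
666,351.46
667,350.53
668,349.6
669,348.66
670,347.68
671,346.65
672,345.59
673,344.5
674,343.4
675,342.31
676,341.24
677,340.21
678,339.22
679,338.3
680,337.45
681,336.69
682,336.02
683,335.41
684,334.87
685,334.37
686,333.92
687,333.5
688,333.11
689,332.72
690,332.34
691,331.95
692,331.54
693,331.12
694,330.68
695,330.2
696,329.7
697,329.15
698,328.56
699,327.92
700,327.23
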