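wavelength_nm	extinction_L_per_cm_mol
380	80000
382	88383.9
384	97896.8
386	108295
388	119185
390	130000
392	139756
394	148462
396	157138
398	167096
400	180000
402	197561
404	219710
406	245453
408	273092
410	3e+05
412	325076
414	349461
416	373246
418	396645
420	420000
422	441099
424	459753
426	480000
428	509045
430	530000
432	525735
434	5e+05
436	461201
438	412873
440	350000
442	272828
444	201388
446	150000
448	113549
450	90000
452	77348.1
454	69267.5
456	63696.8
458	59272
460	55000
462	51009.5
464	47748.4
466	44956.4
468	42428.3
470	40000
472	37650.3
474	35463.1
476	33453.2
478	31630.2
480	30000
482	28533.6
484	27200.1
486	26000.2
488	24933.7
490	24000
492	23148.5
494	22365.6
496	21700.8
498	21198.2
500	20900
502	20822.2
504	20927.4
506	21180.7
508	21549.3
510	22000
512	22553.8
514	23245.3
516	24060.7
518	24984.8
520	26000
522	27134.1
524	28419.1
526	29839.3
528	31374.7
530	33000
532	34777.9
534	36750.4
536	38843.7
538	40964.9
540	43000
542	44923.6
544	46765.6
546	48475.7
548	50000
550	51349
552	52472.8
554	53217.9
556	53413.3
558	52944.9
560	52000
562	50537.5
564	48792.8
566	47288.7
568	45954.4
570	44659.5
572	43361.1
574	42150.8
576	40802.8
578	39084.6
580	37042.4
582	34968.6
584	33152.2
586	31720.1
588	30160.5
590	28000
592	25035.6
594	21787.2
596	18800.1
598	16387.4
600	14700
602	13653.2
604	12968.1
606	12481.8
608	12063.1
610	11600
612	11110.9
614	10665.5
616	10243.2
618	9826.34
620	9400
622	8973.24
624	8557.3
626	8143.9
628	7726.46
630	7300
632	6857.63
634	6409.73
636	5975.12
638	5568.33
640	5200
642	4853.32
644	4520.08
646	4217.34
648	3957.57
650	3750
652	3597.63
654	3485.3
656	3395.86
658	3314.27
660	3227
662	3135.49
664	3048.44
666	2964.37
668	2881.96
670	2800
672	2718.01
674	2636.86
676	2557.46
678	2480.61
680	2407
682	2334.26
684	2260.72
686	2187.92
688	2117.21
690	2049.79
692	1986.69
694	1928.81
696	1876.94
698	1831.78
700	1794
702	1764.33
704	1741.92
706	1725.17
708	1712.62
710	1702.87
712	1694.57
714	1686.41
716	1677.09
718	1665.36
720	1650
722	1629.84
724	1605.64
726	1579.07
728	1551.76
730	1525.18
732	1500.74
734	1479.76
736	1463.49
738	1453.15
740	1450
742	1458.27
744	1479.12
746	1509.33
748	1545.6
750	1584.41
752	1621.85
754	1653.67
756	1675.32
758	1682.21
760	1670
762	1638
764	1590.86
766	1532.73
768	1467.6
770	1399.12
772	1330.44
774	1264.23
776	1202.65
778	1147.44
780	1100
782	1056.89
784	1014.41
786	973.26
788	934.044
790	897.258
792	863.312
794	832.546
796	805.242
798	781.65
800	762
802	746.526
804	734.759
806	725.938
808	719.374
810	714.423
812	710.473
814	706.929
816	703.212
818	698.753
820	693
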