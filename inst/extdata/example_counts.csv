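time_h,class_index,count
0,1,21
0,2,59
0,3,243
0,4,520
0,5,735
0,6,1071
0,7,867
0,8,777
0,9,412
0,10,235
0,11,54
0,12,6
0,13,0
2,1,190
2,2,345
2,3,509
2,4,836
2,5,866
2,6,1102
2,7,608
2,8,279
2,9,168
2,10,70
2,11,26
2,12,1
2,13,0
4,1,323
4,2,527
4,3,1114
4,4,1055
4,5,713
4,6,644
4,7,416
4,8,166
4,9,24
4,10,18
4,11,0
4,12,0
4,13,0
6,1,553
6,2,619
6,3,998
6,4,892
6,5,948
6,6,611
6,7,298
6,8,60
6,9,21
6,10,0
6,11,0
6,12,0
6,13,0
8,1,579
8,2,765
8,3,1050
8,4,899
8,5,842
8,6,452
8,7,309
8,8,81
8,9,19
8,10,1
8,11,3
8,12,0
8,13,0
10,1,413
10,2,564
10,3,788
10,4,1075
10,5,1032
10,6,600
10,7,327
10,8,131
10,9,44
10,10,17
10,11,9
10,12,0
10,13,0
12,1,200
12,2,473
12,3,617
12,4,969
12,5,784
12,6,932
12,7,587
12,8,233
12,9,143
12,10,56
12,11,6
12,12,0
12,13,0
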