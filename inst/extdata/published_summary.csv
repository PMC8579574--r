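method,type,youden,accuracy,f_measure,auc
CART/GUIDE,tree,81.58,91.51,93.04,0.908
J48,tree,85.12,93.38,94.61,0.926
QUEST,tree,79.96,90.49,92.12,0.889
CRUISE,tree,88.03,94.57,95.54,0.940
Ctree,tree,81.23,91.26,92.80,0.906
Evtree,tree,83.49,92.61,93.99,0.918
C50,tree,87.81,94.65,95.64,0.939
LOTUS,tree,39.46,70.97,75.85,0.697
SVM,svm,67.93,84.38,86.88,0.840
England and Fraser (E&F),index,48.82,71.65,72.03,0.744
RBC,index,54.89,79.03,83.02,0.774
Mentzer,index,71.25,86.33,88.69,0.856
Srivastava,index,58.83,78.44,80.61,0.794
Shine and Lal (S&L),index,15.32,66.21,78.06,0.577
Bessman (RDW),index,-15.83,34.38,6.76,0.421
Ricerca,index,3.70,60.95,74.89,0.519
Green and King (G&K),index,62.21,81.15,83.84,0.811
Das Gupta,index,32.87,71.48,79.39,0.664
Jayabose (RDWI),index,57.28,80.64,84.62,0.786
Telmissani—MCHD,index,2.78,60.61,74.76,0.514
Telmissani—MDHL,index,40.70,66.81,65.67,0.704
Huber—Herklotz,index,6.02,46.10,29.52,0.530
Kerman I,index,60.66,83.28,87.22,0.803
Kerman II,index,72.96,86.93,89.08,0.865
Sirdah,index,70.86,84.38,86.06,0.854
Ehsani,index,73.38,87.18,89.31,0.867
Bordbar,index,55.05,81.58,86.43,0.775
Matos and Carvalho,index,57.27,77.93,80.36,0.786
Janel (11 T),index,67.62,82.26,83.76,0.838
CRUISE Index,index,41.87,72.24,77.02,0.709
Index26,index,71.07,84.81,86.63,0.855
Hisham,index,51.70,77.25,81.39,0.759
Hameed,index,11.68,48.81,33.07,0.558
Ravanbakhsh-F1,index,54.11,78.69,82.77,0.771
Ravanbakhsh-F2,index,32.29,68.68,75.12,0.661
Ravanbakhsh-F3,index,50.98,77.76,82.42,0.755
Ravanbakhsh-F4,index,46.34,77.50,83.49,0.732
Zaghloul1,index,4.35,47.96,42.01,0.522
Zaghloul2,index,3.27,47.54,41.81,0.516
Kandhrol1,index,-4.91,48.89,56.06,0.475
Kandhrol2,index,30.29,68.59,75.88,0.671
Alparslan,index,38.71,72.67,79.04,0.694
Merdin1,index,58.60,79.20,81.99,0.793
Merdin2,index,46.40,70.97,72.01,0.732
Roth,index,14.89,66.04,77.97,0.574
Sargolzaie,index,29.79,61.63,60.42,0.649
Keikhaei,index,59.29,80.31,83.49,0.797
Nishad,index,63.96,82.94,85.93,0.819
Wongprachum,index,55.33,78.35,81.83,0.777
Sehgal,index,64.70,85.23,88.72,0.824
Pornprasert (MCHC),index,-32.50,31.32,27.57,0.337
Sirachainan,index,9.45,49.58,41.07,0.547
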